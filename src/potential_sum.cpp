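#include <Rcpp.h>
using namespace Rcpp;

// Pairwise dipole-tensor sums for reciprocity-theorem potential maps.
//
// K(r) = (3 r r^T - |r|^2 I) / (4 pi |r|^5) is the point-dipole kernel:
// the stray field at displacement r of a unit dipole is H = K(r) m.
// Both entry points accumulate over every parent cell and every periodic
// image shift; the singular configuration |r| -> 0 is a hard error because
// callers guarantee the bead centre stays off the cell lattice.

static inline void check_dims(const NumericMatrix& m, int ncol, const char* what) {
  if (m.ncol() != ncol)
    stop("'%s' must have %d columns", what, ncol);
}

// Vf(s) = sum_cells dV * K(r_cell + shift - s) * M_cell   (A/m * m^3 * 1/m^3)
// U(s) = -2 mu0 m_bead . Vf(s)
// [[Rcpp::export]]
NumericMatrix cpp_dipole_vector_sum(NumericMatrix nodes, NumericMatrix cells,
                                    NumericMatrix M, double dV,
                                    NumericMatrix shifts) {
  check_dims(nodes, 3, "nodes");
  check_dims(cells, 3, "cells");
  check_dims(M, 3, "M");
  check_dims(shifts, 3, "shifts");
  if (cells.nrow() != M.nrow())
    stop("'cells' and 'M' must have the same number of rows");
  const int nn = nodes.nrow(), nc = cells.nrow(), ns = shifts.nrow();
  const double c4pi = 1.0 / (4.0 * M_PI);
  NumericMatrix out(nn, 3);

  // expand cells over image shifts once (memory ~ nc*ns*6 doubles)
  std::vector<double> cx((size_t)nc * ns), cy((size_t)nc * ns), cz((size_t)nc * ns);
  std::vector<double> mx((size_t)nc * ns), my((size_t)nc * ns), mz((size_t)nc * ns);
  size_t q = 0;
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < nc; ++c, ++q) {
      cx[q] = cells(c, 0) + shifts(s, 0);
      cy[q] = cells(c, 1) + shifts(s, 1);
      cz[q] = cells(c, 2) + shifts(s, 2);
      mx[q] = M(c, 0); my[q] = M(c, 1); mz[q] = M(c, 2);
    }
  const size_t ntot = q;

  for (int i = 0; i < nn; ++i) {
    const double sx = nodes(i, 0), sy = nodes(i, 1), sz = nodes(i, 2);
    double ax = 0.0, ay = 0.0, az = 0.0;
    for (size_t j = 0; j < ntot; ++j) {
      const double rx = cx[j] - sx, ry = cy[j] - sy, rz = cz[j] - sz;
      const double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 <= 0.0) stop("singular configuration: node coincides with a parent cell centre");
      const double ir2 = 1.0 / r2;
      const double ir5 = ir2 * ir2 / std::sqrt(r2);
      const double mdr = mx[j] * rx + my[j] * ry + mz[j] * rz;
      ax += (3.0 * rx * mdr - mx[j] * r2) * ir5;
      ay += (3.0 * ry * mdr - my[j] * r2) * ir5;
      az += (3.0 * rz * mdr - mz[j] * r2) * ir5;
    }
    out(i, 0) = ax * c4pi * dV;
    out(i, 1) = ay * c4pi * dV;
    out(i, 2) = az * c4pi * dV;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// G(s) = sum_cells dV * K(r_cell + shift - s): symmetric 3x3 per node,
// packed (xx, xy, xz, yy, yz, zz).  For masks magnetized uniformly along a
// unit vector d with magnitude Ms, Vf = Ms * G d, so one tensor map serves
// every field angle of a rotating/switching sequence.
// [[Rcpp::export]]
NumericMatrix cpp_dipole_tensor_sum(NumericMatrix nodes, NumericMatrix cells,
                                    double dV, NumericMatrix shifts) {
  check_dims(nodes, 3, "nodes");
  check_dims(cells, 3, "cells");
  check_dims(shifts, 3, "shifts");
  const int nn = nodes.nrow(), nc = cells.nrow(), ns = shifts.nrow();
  const double c4pi = 1.0 / (4.0 * M_PI);
  NumericMatrix out(nn, 6);

  std::vector<double> cx((size_t)nc * ns), cy((size_t)nc * ns), cz((size_t)nc * ns);
  size_t q = 0;
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < nc; ++c, ++q) {
      cx[q] = cells(c, 0) + shifts(s, 0);
      cy[q] = cells(c, 1) + shifts(s, 1);
      cz[q] = cells(c, 2) + shifts(s, 2);
    }
  const size_t ntot = q;

  for (int i = 0; i < nn; ++i) {
    const double sx = nodes(i, 0), sy = nodes(i, 1), sz = nodes(i, 2);
    double gxx = 0, gxy = 0, gxz = 0, gyy = 0, gyz = 0, gzz = 0;
    for (size_t j = 0; j < ntot; ++j) {
      const double rx = cx[j] - sx, ry = cy[j] - sy, rz = cz[j] - sz;
      const double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 <= 0.0) stop("singular configuration: node coincides with a parent cell centre");
      const double ir2 = 1.0 / r2;
      const double ir5 = ir2 * ir2 / std::sqrt(r2);
      gxx += (3.0 * rx * rx - r2) * ir5;
      gyy += (3.0 * ry * ry - r2) * ir5;
      gzz += (3.0 * rz * rz - r2) * ir5;
      gxy += 3.0 * rx * ry * ir5;
      gxz += 3.0 * rx * rz * ir5;
      gyz += 3.0 * ry * rz * ir5;
    }
    out(i, 0) = gxx * c4pi * dV;
    out(i, 1) = gxy * c4pi * dV;
    out(i, 2) = gxz * c4pi * dV;
    out(i, 3) = gyy * c4pi * dV;
    out(i, 4) = gyz * c4pi * dV;
    out(i, 5) = gzz * c4pi * dV;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
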