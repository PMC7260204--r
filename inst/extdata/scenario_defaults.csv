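scenario,parameter,value,units
disc,bead.radius,4e-6,m
disc,bead.chi,0.0256,1
disc,bead.friction,0.03,1
disc,structure.radius,15e-6,m
disc,structure.thickness,30e-9,m
disc,structure.Js,1.0,T
disc,field.amplitude,20e-3,T
disc,field.frequency,0.9,Hz
disc,fit.N,30,1
disc,fit.sub,3,1
disc,sim.max_dt,7e-4,s
triangles,bead.radius,4e-6,m
triangles,structure.side,15e-6,m
triangles,structure.thickness,50e-9,m
triangles,structure.Js,1.0,T
triangles,field.amplitude,20e-3,T
triangles,field.frequency,1,Hz
triangles,field.angles,30;150,deg
triangles,fit.N,100,1
triangles,fit.copies,100,1
triangles,fit.sub,3,1
stripes,bead.radius,1.4e-6,m
stripes,structure.width,10e-6,m
stripes,structure.thickness,20e-9,m
stripes,structure.Js,1.0,T
stripes,field.frequency,3,Hz
stripes,fit.N,50,1
stripes,fit.copies,50,1
stripes,fit.sub,3,1
ovals,bead.radius,4e-6,m
ovals,structure.length,26e-6,m
ovals,structure.height,21e-6,m
ovals,structure.thickness,50e-9,m
ovals,structure.Js,1.5,T
ovals,field.amplitude,20e-3,T
ovals,field.frequency,1,Hz
ovals,field.n_states,180,1
ovals,field.sense,-1,1
ovals,fit.N,30,1
ovals,fit.sub,3,1
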