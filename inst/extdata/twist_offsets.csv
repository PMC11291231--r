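muscle,twist_class,dx,dy,dz
SOL,low,-0.0008604,-0.0008192,-0.0040958
GM,low,0.0014943,-8.72e-05,-0.0004358
GL,low,-0.0006339,0.0009063,0.0045315
SOL,medium,-0.001299,-5e-04,-0.0025
GM,medium,0.001299,-5e-04,-0.0025
GL,medium,0,0.001,0.005
SOL,high,-0.0014943,-8.72e-05,-0.0004358
GM,high,0.0008604,-0.0008192,-0.0040958
GL,high,0.0006339,0.0009063,0.0045315
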