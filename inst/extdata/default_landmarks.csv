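region,side,x_mm,y_mm,z_mm
GM,left,-51,0,0
GM,right,51,0,0
WM,left,-25,-15,5
WM,right,25,-15,5
HCN,left,-27,8,0
HCN,right,27,8,0
pons,midline,0,-30,-28
cerebellum,left,-21,-36,-24
cerebellum,right,21,-36,-24
CSF,left,-10,28,4
CSF,right,10,28,4
reference,midline,82,0,-10
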