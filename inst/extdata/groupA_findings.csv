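subject,contour,observation,present
A1,MD,collagen,1
A2,MD,collagen,1
A3,MD,collagen,1
A4,MD,collagen,0
A5,MD,collagen,0
A1,CON,collagen,0
A2,CON,collagen,0
A3,CON,collagen,0
A4,CON,collagen,0
A5,CON,collagen,0
A1,MD,red_blood_cell_proliferation,1
A2,MD,red_blood_cell_proliferation,1
A3,MD,red_blood_cell_proliferation,1
A4,MD,red_blood_cell_proliferation,1
A5,MD,red_blood_cell_proliferation,0
A1,MD,fibrosis,1
A2,MD,fibrosis,1
A3,MD,fibrosis,1
A4,MD,inflammation,1
A5,MD,inflammation,1
A1,MD,mineralization,1
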