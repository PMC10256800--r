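subject,contour,diagnosis,strength_label
C,HHV,multinucleated_macrophages,minimal
D,HHV,fibrosis,minimal
D,HHV,inflammation,mild
E,HHV,histiocytosis,minimal
A,HLV,chondrocyte_necrosis,marked
B,HLV,chondrocyte_necrosis,moderate
C,HLV,chondrocyte_necrosis,moderate
D,HLV,chondrocyte_necrosis,moderate
E,HLV,chondrocyte_necrosis,moderate
A,HLV,inflammation,marked
B,HLV,inflammation,moderate
C,HLV,inflammation,moderate
D,HLV,inflammation,moderate
E,HLV,inflammation,moderate
A,HLV,fibrosis,marked
B,HLV,fibrosis,moderate
C,HLV,fibrosis,moderate
D,HLV,fibrosis,moderate
E,HLV,fibrosis,mild
A,HLV,histiocytosis,moderate
B,HLV,histiocytosis,moderate
C,HLV,histiocytosis,moderate
D,HLV,histiocytosis,moderate
A,HLV,multinucleated_giant_cells,mild
B,HLV,multinucleated_giant_cells,mild
C,HLV,multinucleated_giant_cells,mild
A,HLV,bronchitis,moderate
B,HLV,bronchitis,moderate
C,HLV,bronchitis,moderate
A,HLV,bronchial_ulceration,moderate
B,HLV,bronchial_ulceration,moderate
A,LLV,chondrocyte_necrosis,mild-moderate
B,LLV,chondrocyte_necrosis,minimal-mild
C,LLV,chondrocyte_necrosis,minimal-mild
D,LLV,chondrocyte_necrosis,minimal
E,LLV,chondrocyte_necrosis,minimal
A,LLV,inflammation,mild
B,LLV,inflammation,minimal
C,LLV,inflammation,minimal
A,LLV,fibrosis,minimal-mild
B,LLV,fibrosis,minimal
C,LLV,fibrosis,minimal
A,MD,chondrocyte_necrosis,moderate
B,MD,chondrocyte_necrosis,moderate
C,MD,chondrocyte_necrosis,moderate
D,MD,chondrocyte_necrosis,moderate
E,MD,chondrocyte_necrosis,moderate
A,MD,inflammation,marked
B,MD,inflammation,moderate
C,MD,inflammation,moderate
D,MD,inflammation,moderate
E,MD,inflammation,moderate
A,MD,fibrosis,marked
B,MD,fibrosis,moderate
C,MD,fibrosis,marked
D,MD,fibrosis,moderate
E,MD,fibrosis,moderate
A,MD,type2_pneumocyte_hyperplasia,mild
B,MD,type2_pneumocyte_hyperplasia,mild
C,MD,type2_pneumocyte_hyperplasia,mild
D,MD,type2_pneumocyte_hyperplasia,mild
E,MD,type2_pneumocyte_hyperplasia,mild
A,MD,alveolar_septa_thickening,moderate
B,MD,alveolar_septa_thickening,moderate
C,MD,alveolar_septa_thickening,moderate
D,MD,alveolar_septa_thickening,moderate
A,MD,multinucleated_giant_cells,mild
B,MD,multinucleated_giant_cells,mild
C,MD,multinucleated_giant_cells,mild
D,MD,multinucleated_giant_cells,mild
A,MD,histiocytosis,moderate
B,MD,histiocytosis,moderate
C,MD,histiocytosis,moderate
A,MD,bronchitis,moderate
B,MD,bronchitis,moderate
C,MD,bronchitis,moderate
A,MD,bronchial_ulceration,moderate
B,MD,bronchial_ulceration,moderate
C,MD,vascular_proliferation,moderate
C,MD,neovascularization,moderate
C,MD,vascular_necrosis,moderate
A,MD,proteinaceous_fluid,moderate
C,MD,proteinaceous_fluid,moderate
D,MD,proteinaceous_fluid,moderate
A,LDF,chondrocyte_necrosis,mild
B,LDF,chondrocyte_necrosis,minimal-mild
B,LDF,fibrosis,moderate
C,LDF,fibrosis,moderate
D,LDF,fibrosis,mild
E,LDF,fibrosis,mild
C,LDF,inflammation,mild
D,LDF,inflammation,mild
E,LDF,inflammation,mild
C,LDF,neovascularization,minimal
E,LDF,neovascularization,minimal
A,LDNF,multinucleated_macrophages,minimal-mild
B,LDNF,multinucleated_macrophages,minimal-mild
C,LDNF,multinucleated_macrophages,minimal-mild
D,LDNF,multinucleated_macrophages,minimal-mild
E,LDNF,multinucleated_macrophages,minimal-mild
A,LDNF,chondrocyte_necrosis,minimal
B,LDNF,chondrocyte_necrosis,minimal
C,NDF,fibrosis,moderate
C,NDF,inflammation,moderate
C,NDF,chondrocyte_necrosis,mild
C,NDF,histiocytosis,mild
C,NDF,multinucleated_giant_cells,mild
C,NDF,vascular_proliferation,minimal
C,NDF,proteinaceous_fluid,minimal
D,NDF,histiocytosis,minimal
E,NDF,inflammation,mild
E,NDF,fibrosis,mild
A,NDNF,fibrosis,minimal-mild
A,NDNF,inflammation,minimal-mild
A,NDNF,chondrocyte_necrosis,minimal
A,NDNF,multinucleated_giant_cells,minimal
A,NDNF,vascular_proliferation,minimal
B,NDNF,inflammation,minimal
C,NDNF,chondrocyte_necrosis,minimal
D,NDNF,fibrosis,mild
D,NDNF,inflammation,mild
D,NDNF,multinucleated_giant_cells,minimal
D,NDNF,vascular_proliferation,minimal
B,CON,inflammation,minimal
E,CON,type2_pneumocyte_hyperplasia,minimal
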