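label,csrd,ipemrd
tumor,21088,510
lymphocyte,13575,207
fibroblast,8639,230
unlabeled,7518,150
plasma_cell,5557,161
macrophage,1353,42
vascular_endothelium,514,48
ductal_epithelium,498,0
apoptotic_body,391,13
mitotic_figure,229,5
myoepithelium,55,0
neutrophil,45,6
eosinophil,3,0
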