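,Uyghur,Uzbek,Kirghiz,Kazakh,Salar,Tu,Dongxiang,Yugur,Baoan,Mongol,Hui,Han_XJ,Han_XA
Uyghur,0,0.0398,0.0291,0.0305,0.0477,0.0508,0.0483,0.0496,0.038,0.0427,0.051,0.0476,0.0554
Uzbek,0.0398,0,0.0271,0.0188,0.0426,0.0324,0.0377,0.0396,0.0363,0.0385,0.0519,0.0357,0.0188
Kirghiz,0.0291,0.0271,0,0.0256,0.0411,0.0419,0.048,0.0509,0.0403,0.0402,0.0548,0.0407,0.05
Kazakh,0.0305,0.0188,0.0256,0,0.0331,0.0315,0.0351,0.039,0.0301,0.0314,0.0395,0.0327,0.06
Salar,0.0477,0.0426,0.0411,0.0331,0,0.0136,0.0172,0.0293,0.0114,0.0156,0.0265,0.0138,0.0446
Tu,0.0508,0.0324,0.0419,0.0315,0.0136,0,0.0092,0.0221,0.015,0.0179,0.0284,0.0102,0.0265
Dongxiang,0.0483,0.0377,0.048,0.0351,0.0172,0.0092,0,0.0244,0.0164,0.0204,0.0254,0.0116,0.0243
Yugur,0.0496,0.0396,0.0509,0.039,0.0293,0.0221,0.0244,0,0.0256,0.0328,0.0383,0.024,0.0208
Baoan,0.038,0.0363,0.0403,0.0301,0.0114,0.015,0.0164,0.0256,0,0.0164,0.0257,0.0134,0.0361
Mongol,0.0427,0.0385,0.0402,0.0314,0.0156,0.0179,0.0204,0.0328,0.0164,0,0.0247,0.018,0.0226
Hui,0.051,0.0519,0.0548,0.0395,0.0265,0.0284,0.0254,0.0383,0.0257,0.0247,0,0.0223,0.023
Han_XJ,0.0476,0.0357,0.0407,0.0327,0.0138,0.0102,0.0116,0.024,0.0134,0.018,0.0223,0,0.0245
Han_XA,0.0554,0.0188,0.05,0.06,0.0446,0.0265,0.0243,0.0208,0.0361,0.0226,0.023,0.0245,0
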