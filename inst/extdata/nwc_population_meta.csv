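name,chromosomes,longitude,latitude,phylum,family,language,religion
Han_XA,168,108.57,34.16,Sino-Tibetan,Sinitic,Mandarin,No specific
Hui,164,106.28,38.02,Sino-Tibetan,Sinitic,Mandarin,Islamic
Mongol,188,111.67,40.92,Altaic,Mongolian,Mongolian,Lamaism
Uyghur,176,76.50,37.60,Altaic,Turkic,Uyghur,Islamic
Kazakh,200,82.50,43.50,Altaic,Turkic,Kazakh,Islamic
Uzbek,116,81.20,43.55,Altaic,Turkic,Uzbek,Islamic
Kirghiz,201,75.43,40.33,Altaic,Turkic,Kirghiz,Islamic
Salar,200,102.28,35.50,Altaic,Turkic,Salar,Islamic
Tu,204,101.57,36.50,Altaic,Mongolian,Monguor,Lamaism
Dongxiang,236,102.70,35.80,Altaic,Mongolian,Santa,Islamic
Yugur,240,100.50,37.20,Altaic,Mongolian,East Yugur,Islamic
Baoan,240,100.16,33.10,Altaic,Mongolian,Bonan,Islamic
Han_XJ,300,87.38,43.92,Sino-Tibetan,Sinitic,Mandarin,No specific
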