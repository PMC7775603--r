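name,family,subgroup
Mandarin,Sinitic,
Cantonese,Sinitic,
Tamil,Dravidian,
Telugu,Dravidian,
Basque_Central,Basque,
Basque_Western,Basque,
Archi,NE-Caucasian,
Lak,NE-Caucasian,
Mari_1,Uralic,Mari
Mari_2,Uralic,Mari
Udmurt_1,Uralic,Permic
Udmurt_2,Uralic,Permic
Hungarian,Uralic,Ugric
Khanty_1,Uralic,Ugric
Khanty_2,Uralic,Ugric
Estonian,Uralic,Balto-Finnic
Finnish,Uralic,Balto-Finnic
Kazakh,Turkic,Kipchak
Kirghiz,Turkic,Kipchak
Turkish,Turkic,
Yakut,Turkic,
Uzbek,Turkic,
Evenki,Tungusic,
Even_1,Tungusic,
Even_2,Tungusic,
Buryat,Mongolic,
Yukaghir,Yukaghir,
Korean,Korean,
Japanese,Japanese,
Malagasy,Austronesian,
Irish,IE,Celtic
Welsh,IE,Celtic
Marathi,IE,Indo-Aryan
Hindi,IE,Indo-Aryan
Pashto,IE,Iranian
Greek,IE,Greek
Greek_Cypriot,IE,Greek
Greek_Calabria_1,IE,Greek
Greek_Calabria_2,IE,Greek
Greek_Salento,IE,Greek
Bulgarian,IE,Slavic
Serbo-Croatian,IE,Slavic
Slovenian,IE,Slavic
Polish,IE,Slavic
Russian,IE,Slavic
Faroese,IE,Germanic
Norwegian,IE,Germanic
Danish,IE,Germanic
Icelandic,IE,Germanic
German,IE,Germanic
Dutch,IE,Germanic
English,IE,Germanic
Afrikaans,IE,Germanic
French,IE,Romance
Casalasco,IE,Romance
Reggio_Emilia,IE,Romance
Parma,IE,Romance
Spanish,IE,Romance
Portuguese,IE,Romance
Romanian,IE,Romance
Siciliano_Ragusa,IE,Romance
Siciliano_Mussomeli,IE,Romance
Salentino,IE,Romance
Calabrese_Southern,IE,Romance
Italian,IE,Romance
Barese,IE,Romance
Campano,IE,Romance
Teramano,IE,Romance
Calabrese_Northern,IE,Romance
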