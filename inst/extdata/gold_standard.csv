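group,members,upgma,beast
Sinitic,Mandarin;Cantonese,YES,YES
Dravidian,Tamil;Telugu,YES,YES
Basque,Basque_Central;Basque_Western,YES,YES
Uralic,Mari_1;Mari_2;Udmurt_1;Udmurt_2;Hungarian;Khanty_1;Khanty_2;Estonian;Finnish,YES,NO
Altaic,Kazakh;Kirghiz;Turkish;Yakut;Uzbek;Evenki;Even_1;Even_2;Buryat,YES,NO
IE,Irish;Welsh;Marathi;Hindi;Pashto;Greek;Greek_Cypriot;Greek_Calabria_1;Greek_Calabria_2;Greek_Salento;Bulgarian;Serbo-Croatian;Slovenian;Polish;Russian;Faroese;Norwegian;Danish;Icelandic;German;Dutch;English;Afrikaans;French;Casalasco;Reggio_Emilia;Parma;Spanish;Portuguese;Romanian;Siciliano_Ragusa;Siciliano_Mussomeli;Salentino;Calabrese_Southern;Italian;Barese;Campano;Teramano;Calabrese_Northern,YES,YES
NE-Caucasian,Archi;Lak,YES,YES
Balto-Finnic,Estonian;Finnish,YES,YES
Ugric,Hungarian;Khanty_1;Khanty_2,YES,YES
Turkic,Kazakh;Kirghiz;Turkish;Yakut;Uzbek,YES,YES
Tungusic,Evenki;Even_1;Even_2,YES,YES
Kipchak,Kazakh;Kirghiz,YES,YES
Celtic,Irish;Welsh,YES,YES
Indo-Iranian,Hindi;Marathi;Pashto,YES,YES
Greek,Greek;Greek_Cypriot;Greek_Calabria_1;Greek_Calabria_2;Greek_Salento,YES,YES
Slavic,Bulgarian;Serbo-Croatian;Slovenian;Polish;Russian,YES,YES
Germanic,Faroese;Norwegian;Danish;Icelandic;German;Dutch;English;Afrikaans,YES,YES
Romance,French;Spanish;Portuguese;Romanian;Italian;Casalasco;Parma;Reggio_Emilia;Siciliano_Ragusa;Siciliano_Mussomeli;Salentino;Calabrese_Southern;Barese;Campano;Teramano;Calabrese_Northern,YES,YES
Indo-Aryan,Hindi;Marathi,YES,YES
South-Slavic,Bulgarian;Serbo-Croatian;Slovenian,NO,NO
North Germanic,Faroese;Norwegian;Danish;Icelandic,NO,YES
West Germanic,German;Dutch;Afrikaans;English,NO,YES
Continental West-Germanic,German;Dutch;Afrikaans,YES,YES
Ibero-Romance,Spanish;Portuguese,YES,YES
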