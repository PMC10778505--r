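# synthetic DVS-style example generated by generate_sorption(sorption_scenario(seed = 7, n_replicates = 1)); temperatures in degC
branch,temperature,aw,xe
adsorption,25,0.090000000000000,0.0259991099714503
adsorption,25,0.142857142857143,0.0314140580312947
adsorption,25,0.195714285714286,0.0446637352068790
adsorption,25,0.248571428571429,0.0573415637591632
adsorption,25,0.301428571428571,0.0682148492418572
adsorption,25,0.354285714285714,0.0801347511092964
adsorption,25,0.407142857142857,0.0952883872919095
adsorption,25,0.460000000000000,0.1052170687714938
adsorption,25,0.512857142857143,0.1173174193943748
adsorption,25,0.565714285714286,0.1328614249982881
adsorption,25,0.618571428571429,0.1405788476383886
adsorption,25,0.671428571428571,0.1566014573264617
adsorption,25,0.724285714285714,0.1669590783686083
adsorption,25,0.777142857142857,0.1742028986029814
adsorption,25,0.830000000000000,0.1884413170631559
desorption,25,0.090000000000000,0.0287873613660434
desorption,25,0.142857142857143,0.0421622803682903
desorption,25,0.195714285714286,0.0592533596970005
desorption,25,0.248571428571429,0.0756063497153327
desorption,25,0.301428571428571,0.0931793830003249
desorption,25,0.354285714285714,0.1083176050189266
desorption,25,0.407142857142857,0.1233404248565379
desorption,25,0.460000000000000,0.1396982024318719
desorption,25,0.512857142857143,0.1493397429511678
desorption,25,0.565714285714286,0.1695717431472286
desorption,25,0.618571428571429,0.1821927232735213
desorption,25,0.671428571428571,0.1980228996797404
desorption,25,0.724285714285714,0.2122985169765434
desorption,25,0.777142857142857,0.2236552095879736
desorption,25,0.830000000000000,0.2394918098981729
adsorption,35,0.090000000000000,0.0309399608157450
adsorption,35,0.142857142857143,0.0455246190413981
adsorption,35,0.195714285714286,0.0535303319583253
adsorption,35,0.248571428571429,0.0612673946150367
adsorption,35,0.301428571428571,0.0681870368948185
adsorption,35,0.354285714285714,0.0753752954407060
adsorption,35,0.407142857142857,0.0861126677236785
adsorption,35,0.460000000000000,0.0899076911883942
adsorption,35,0.512857142857143,0.1004430130807483
adsorption,35,0.565714285714286,0.1108209428414921
adsorption,35,0.618571428571429,0.1232316743064977
adsorption,35,0.671428571428571,0.1314981859375416
adsorption,35,0.724285714285714,0.1463983606231188
adsorption,35,0.777142857142857,0.1610366755299183
adsorption,35,0.830000000000000,0.1831148619791531
desorption,35,0.090000000000000,0.0416831084929568
desorption,35,0.142857142857143,0.0600143924776444
desorption,35,0.195714285714286,0.0704841141178010
desorption,35,0.248571428571429,0.0800526775075313
desorption,35,0.301428571428571,0.0915985671485934
desorption,35,0.354285714285714,0.0989239266541265
desorption,35,0.407142857142857,0.1093375968749930
desorption,35,0.460000000000000,0.1204876427109182
desorption,35,0.512857142857143,0.1343601904552619
desorption,35,0.565714285714286,0.1446957194662879
desorption,35,0.618571428571429,0.1579950173061437
desorption,35,0.671428571428571,0.1696301296349360
desorption,35,0.724285714285714,0.1916964945309908
desorption,35,0.777142857142857,0.2130896980390330
desorption,35,0.830000000000000,0.2372661376354107
adsorption,45,0.090000000000000,0.0357867997253525
adsorption,45,0.142857142857143,0.0462551691663047
adsorption,45,0.195714285714286,0.0551946373035132
adsorption,45,0.248571428571429,0.0628223781030581
adsorption,45,0.301428571428571,0.0691278914768085
adsorption,45,0.354285714285714,0.0779581202388950
adsorption,45,0.407142857142857,0.0850135997098858
adsorption,45,0.460000000000000,0.0943025441192769
adsorption,45,0.512857142857143,0.1041540935833460
adsorption,45,0.565714285714286,0.1142004959997326
adsorption,45,0.618571428571429,0.1269142464591412
adsorption,45,0.671428571428571,0.1403266409229403
adsorption,45,0.724285714285714,0.1611272666327801
adsorption,45,0.777142857142857,0.1867786761312869
adsorption,45,0.830000000000000,0.2206155455391776
desorption,45,0.090000000000000,0.0436725953232340
desorption,45,0.142857142857143,0.0579398427374371
desorption,45,0.195714285714286,0.0692242709537177
desorption,45,0.248571428571429,0.0797117877995050
desorption,45,0.301428571428571,0.0938823251035215
desorption,45,0.354285714285714,0.0991466775595333
desorption,45,0.407142857142857,0.1085263751892473
desorption,45,0.460000000000000,0.1196527154846380
desorption,45,0.512857142857143,0.1313356976931367
desorption,45,0.565714285714286,0.1450536145569865
desorption,45,0.618571428571429,0.1632402860480938
desorption,45,0.671428571428571,0.1841312604837287
desorption,45,0.724285714285714,0.2104567503833639
desorption,45,0.777142857142857,0.2414938071852375
desorption,45,0.830000000000000,0.2922375029713178
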