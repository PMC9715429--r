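source_label,canonical_label
Orbulina universa,Orbulina universa
Globigerinoides conglobatus,Globigerinoides conglobatus
Globigerinoides ruber,Globigerinoides ruber
Globigerinoides ruber ruber,Globigerinoides ruber
Globigerinoides ruber albus,Globigerinoides ruber
Globoturborotalita tenella,Globoturborotalita tenella
Trilobatus sacculifer,Trilobatus sacculifer
Sphaeroidinella dehiscens,Sphaeroidinella dehiscens
Globigerinella siphonifera,Globigerinella siphonifera
Globigerinella calida,Globigerinella calida
Globigerinella adamsi,Globigerinella adamsi
Globigerina bulloides,Globigerina bulloides
Globigerina falconensis,Globigerina falconensis
Beella digitata,Beella digitata
Globoturborotalita rubescens,Globoturborotalita rubescens
Turborotalita humilis,Turborotalita humilis
Turborotalita quinqueloba,Turborotalita quinqueloba
Turborotalita clarkei,Turborotalita clarkei
Neogloboquadrina pachyderma,Neogloboquadrina pachyderma
Neogloboquadrina incompta,Neogloboquadrina incompta
P/D intergrade,Neogloboquadrina incompta
Neogloboquadrina dutertrei,Neogloboquadrina dutertrei
Globoquadrina conglomerata,Globoquadrina conglomerata
Pulleniatina obliquiloculata,Pulleniatina obliquiloculata
Globorotalia inflata,Globorotalia inflata
Globorotalia truncatulinoides,Globorotalia truncatulinoides
Globorotalia crassaformis,Globorotalia crassaformis
Globorotalia hirsuta,Globorotalia hirsuta
Globorotalia scitula,Globorotalia scitula
Globorotalia menardii,Globorotalia menardii
Globorotalia tumida,Globorotalia tumida
Globorotalia ungulata,Globorotalia ungulata
Globorotalia cavernula,Globorotalia cavernula
Globorotalia theyeri,Globorotalia theyeri
Candeina nitida,Candeina nitida
Globigerinita glutinata,Globigerinita glutinata
Globigerinita uvula,Globigerinita uvula
Globigerinita minuta,Globigerinita minuta
Tenuitella iota,Tenuitella iota
Berggrenia pumilio,Berggrenia pumilio
Hastigerina pelagica,Hastigerina pelagica
Hastigerinella digitata,Hastigerinella digitata
Dentigloborotalia anfracta,Dentigloborotalia anfracta
Globorotaloides hexagonus,Globorotaloides hexagonus
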