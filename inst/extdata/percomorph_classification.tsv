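name	rank	parent	flags
Paracanthopterygii	division		
Percopsaria	series	Paracanthopterygii	
Percopsiformes	order	Percopsaria	
Zeiogadaria	series	Paracanthopterygii	
Zeiariae	subseries	Zeiogadaria	
Zeiformes	order	Zeiariae	
Cyttoidei	suborder	Zeiformes	
Cyttidae	family	Cyttoidei	not_examined
Zeiodei	suborder	Zeiformes	
Parazenidae	family	Zeiodei	
Zeidae	family	Zeiodei	
Zeniontidae	family	Zeiodei	
Grammicolepididae	family	Zeiodei	not_examined
Oreosomatidae	family	Zeiodei	not_examined
Gadariae	subseries	Zeiogadaria	
Stylephoriformes	order	Gadariae	
Gadiformes	order	Gadariae	
Acanthopterygii	division		
Berycimorphaceae	subdivision	Acanthopterygii	
Beryciformes	order	Berycimorphaceae	
Berycoidei	suborder	Beryciformes	
Stephanoberycoidei	suborder	Beryciformes	
Trachichthyiformes	order	Berycimorphaceae	
Holocentrimorphaceae	subdivision	Acanthopterygii	
Holocentriformes	order	Holocentrimorphaceae	
Percomorphaceae	subdivision	Acanthopterygii	
Ophidiaria	series	Percomorphaceae	
Ophidiiformes	order	Ophidiaria	
Ophidioidei	suborder	Ophidiiformes	
Bythitoidei	suborder	Ophidiiformes	
Batrachoidaria	series	Percomorphaceae	
Batrachoidiformes	order	Batrachoidaria	
Pelagiaria	series	Percomorphaceae	
Scombriformes	order	Pelagiaria	
Syngnatharia	series	Percomorphaceae	
Syngnathiformes	order	Syngnatharia	
Syngnathoidei	suborder	Syngnathiformes	
Dactylopteroidei	suborder	Syngnathiformes	
Callionymoidei	suborder	Syngnathiformes	
Mulloidei	suborder	Syngnathiformes	
Gobiaria	series	Percomorphaceae	
Kurtiformes	order	Gobiaria	
Kurtoidei	suborder	Kurtiformes	
Apogonoidei	suborder	Kurtiformes	
Gobiiformes	order	Gobiaria	
Trichonotoidei	suborder	Gobiiformes	
Gobioidei	suborder	Gobiiformes	
Anabantaria	series	Percomorphaceae	
Synbranchiformes	order	Anabantaria	
Mastacembeloidei	suborder	Synbranchiformes	
Indostomoidei	suborder	Synbranchiformes	
Synbranchoidei	suborder	Synbranchiformes	
Anabantiformes	order	Anabantaria	
Anabantoidei	suborder	Anabantiformes	
Channoidei	suborder	Anabantiformes	
Nandoidei	suborder	Anabantiformes	
Carangaria	series	Percomorphaceae	
Centropomidae	family	Carangaria	incertae_sedis
Lactariidae	family	Carangaria	incertae_sedis
Leptobramidae	family	Carangaria	incertae_sedis
Menidae	family	Carangaria	incertae_sedis
Polynemidae	family	Carangaria	incertae_sedis
Sphyraenidae	family	Carangaria	incertae_sedis
Toxotidae	family	Carangaria	incertae_sedis
Istiophoriformes	order	Carangaria	
Carangiformes	order	Carangaria	non_monophyletic_declared
Pleuronectiformes	order	Carangaria	
Psettodoidei	suborder	Pleuronectiformes	
Pleuronectoidei	suborder	Pleuronectiformes	
"Cyclopsettidae"	family	Pleuronectoidei	
Paralichthodidae	family	Pleuronectoidei	not_examined
Ovalentaria	series	Percomorphaceae	
Ambassidae	family	Ovalentaria	incertae_sedis
Congrogadidae	family	Ovalentaria	incertae_sedis
Embiotocidae	family	Ovalentaria	incertae_sedis
Grammatidae	family	Ovalentaria	incertae_sedis;non_monophyletic_declared
Opistognathidae	family	Ovalentaria	incertae_sedis
Plesiopidae	family	Ovalentaria	incertae_sedis
Polycentridae	family	Ovalentaria	incertae_sedis
Pomacentridae	family	Ovalentaria	incertae_sedis
Pseudochromidae	family	Ovalentaria	incertae_sedis
Cichlomorphae	superorder	Ovalentaria	
Cichliformes	order	Cichlomorphae	
Atherinomorphae	superorder	Ovalentaria	
Atheriniformes	order	Atherinomorphae	
Atherinoidei	suborder	Atheriniformes	
Atherinopsoidei	suborder	Atheriniformes	
Beloniformes	order	Atherinomorphae	
Adrianichthyoidei	suborder	Beloniformes	
Belonoidei	suborder	Beloniformes	
Cyprinodontiformes	order	Atherinomorphae	
Aplocheiloidei	suborder	Cyprinodontiformes	
Aplocheilidae	family	Aplocheiloidei	
Nothobranchiidae	family	Aplocheiloidei	not_examined
"Rivulidae"	family	Aplocheiloidei	not_examined
Cyprinodontoidei	suborder	Cyprinodontiformes	
Cyprinodontidae	family	Cyprinodontoidei	
Fundulidae	family	Cyprinodontoidei	
Poeciliidae	family	Cyprinodontoidei	
"Pantanodontidae"	family	Cyprinodontoidei	not_examined
Mugilomorphae	superorder	Ovalentaria	
Mugiliformes	order	Mugilomorphae	
Blenniimorphae	superorder	Ovalentaria	
Gobiesociformes	order	Blenniimorphae	
Blenniiformes	order	Blenniimorphae	
Eupercaria	series	Percomorphaceae	
Callanthiidae	family	Eupercaria	incertae_sedis
Centrogenyidae	family	Eupercaria	incertae_sedis
Emmelichthyidae	family	Eupercaria	incertae_sedis
Malacanthidae	family	Eupercaria	incertae_sedis
Monodactylidae	family	Eupercaria	incertae_sedis
Moronidae	family	Eupercaria	incertae_sedis
Pomacanthidae	family	Eupercaria	incertae_sedis
Scatophagidae	family	Eupercaria	incertae_sedis
Sciaenidae	family	Eupercaria	incertae_sedis
Siganidae	family	Eupercaria	incertae_sedis
Sillaginidae	family	Eupercaria	incertae_sedis
Dinolestidae	family	Eupercaria	incertae_sedis;not_examined
Dinopercidae	family	Eupercaria	incertae_sedis;not_examined
Parascorpididae	family	Eupercaria	incertae_sedis;not_examined
Gerreiformes	order	Eupercaria	
Uranoscopiformes	order	Eupercaria	
Labriformes	order	Eupercaria	
Ephippiformes	order	Eupercaria	
Chaetodontiformes	order	Eupercaria	
Acanthuriformes	order	Eupercaria	
Lutjaniformes	order	Eupercaria	
Lobotiformes	order	Eupercaria	
Spariformes	order	Eupercaria	
Priacanthiformes	order	Eupercaria	
Caproiformes	order	Eupercaria	
Lophiiformes	order	Eupercaria	
Lophioidei	suborder	Lophiiformes	
Antennarioidei	suborder	Lophiiformes	
Chaunacoidei	suborder	Lophiiformes	
Ogcocephaloidei	suborder	Lophiiformes	
Ceratioidei	suborder	Lophiiformes	
Tetraodontiformes	order	Eupercaria	
Triodontoidei	suborder	Tetraodontiformes	
Triacanthoidei	suborder	Tetraodontiformes	
Triacanthodoidei	suborder	Tetraodontiformes	
Tetraodontoidei	suborder	Tetraodontiformes	
Moloidei	suborder	Tetraodontiformes	
Balistoidei	suborder	Tetraodontiformes	
Ostracioidei	suborder	Tetraodontiformes	
Pempheriformes	order	Eupercaria	
"Percophidae"	family	Pempheriformes	
Centrarchiformes	order	Eupercaria	
Centrarchoidei	suborder	Centrarchiformes	
Cirrhitoidei	suborder	Centrarchiformes	
Percichthyoidei	suborder	Centrarchiformes	
Percalatoidei	suborder	Centrarchiformes	
"Percalatidae"	family	Percalatoidei	
Terapontoidei	suborder	Centrarchiformes	
Perciformes	order	Eupercaria	
Bembropoidei	suborder	Perciformes	
Normanichthyoidei	suborder	Perciformes	
Serranoidei	suborder	Perciformes	
Percoidei	suborder	Perciformes	
Notothenioidei	suborder	Perciformes	
Scorpaenoidei	suborder	Perciformes	
Platycephaloidei	suborder	Perciformes	
Triglioidei	suborder	Perciformes	
Cottoidei	suborder	Perciformes	
Anoplopomatales	infraorder	Cottoidei	
Zoarcales	infraorder	Cottoidei	
Gasterosteales	infraorder	Cottoidei	
Zaniolepidoales	infraorder	Cottoidei	
Hexagrammales	infraorder	Cottoidei	
Cottales	infraorder	Cottoidei	
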