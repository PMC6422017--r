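(Ailuropoda_melanoleuca,((Plionarctos_edenensis,(Arctodus_simus,((Arctotherium_angustidens,(Arctotherium_vetustum,(Arctotherium_bonariense,(Arctotherium_tarijense,Arctotherium_wingei)))),(Tremarctos_floridanus,Tremarctos_ornatus)))),(Melursus_ursinus,(((Ursus_americanus,Ursus_thibetanus),Helarctos_malayanus),(Ursus_arctos,Ursus_maritimus)))));
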