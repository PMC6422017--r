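tip_label,subfamily,habitat
Ailuropoda_melanoleuca,Ailuropodinae,closed
Plionarctos_edenensis,Tremarctinae,closed
Arctodus_simus,Tremarctinae,open
Arctotherium_angustidens,Tremarctinae,open
Arctotherium_vetustum,Tremarctinae,open
Arctotherium_bonariense,Tremarctinae,open
Arctotherium_tarijense,Tremarctinae,open
Arctotherium_wingei,Tremarctinae,closed
Tremarctos_floridanus,Tremarctinae,closed
Tremarctos_ornatus,Tremarctinae,closed
Melursus_ursinus,Ursinae,closed
Ursus_americanus,Ursinae,closed
Ursus_thibetanus,Ursinae,closed
Helarctos_malayanus,Ursinae,closed
Ursus_arctos,Ursinae,open
Ursus_maritimus,Ursinae,open
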