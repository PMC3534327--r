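key	count
proteome	20242
sp_total	5676
tm_total	5458
tm_lacking_sp	3539
sp_only	3757
removed_endomembrane	207
removed_mitochondrial	66
tm_organelle_assigned	481
chemoreceptors	1469
channels	343
transporters	484
enzymes	517
signaling	354
trafficking	65
adhesion	58
ECM	54
other	805
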