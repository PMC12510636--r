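synthetic example inputs (see ?readThresholds, ?readDockingEnergies); the docking table is synthetic toy data, not measured energies
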