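Drop-in directory for the two AlphaFold v4 worked-example structures:

    AF-P48594-F1-model_v4.pdb   (human SERPINB4; expected 10 charged stickers)
    AF-P36871-F1-model_v4.pdb   (human PGM1; expected 11 charged stickers)

They are not bundled (size budget / offline build). After placing them
here, reinstall the package; acceptance criterion 1 in the test suite
and targets t1/t2 in scripts/acceptance.R will then be computed.
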