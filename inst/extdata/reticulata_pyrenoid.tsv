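tip	pyrenoid
typhlos	present
difformis	present
rosae	absent
chlorococcoides	present
reticulata	absent
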