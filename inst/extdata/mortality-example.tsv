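# per-stage increased mortality (percent over wild-type control)
FBdv:00005289	30
FBdv:00005336	40
FBdv:00005342	0
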