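((a0[&&NHX:S=A],(c[&&NHX:S=C],(a[&&NHX:S=A],(d2[&&NHX:S=D],(a2[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S:xfer=1])[&&NHX:ev=T:xfer=1])[&&NHX:ev=T:xfer=1])[&&NHX:ev=T])[&&NHX:ev=S],d1[&&NHX:S=D])[&&NHX:ev=S];
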