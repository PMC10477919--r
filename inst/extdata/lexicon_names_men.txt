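# given names resolved to "man" (starter list, en + es)
james
john
robert
michael
david
william
richard
thomas
charles
daniel
matthew
george
paul
mark
andrew
peter
carlos
josé
jose
juan
luis
miguel
pedro
javier
antonio
francisco
alejandro
diego
fernando
sergio
omar
ahmed
mohammed
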