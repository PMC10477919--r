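# given names resolved to "woman" (starter list, en + es)
mary
patricia
jennifer
linda
elizabeth
barbara
susan
jessica
sarah
karen
emma
olivia
sophia
emily
grace
hannah
maría
maria
carmen
ana
isabel
laura
marta
lucía
lucia
elena
sofía
sofia
paula
claudia
valeria
fatima
aisha
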