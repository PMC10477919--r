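# organization cue terms (one per line, matched case-insensitively as words)
ministry
ministerio
department
departamento
agency
agencia
official
oficial
government
gobierno
health
salud
news
noticias
university
universidad
institute
instituto
organization
organisation
foundation
fundación
council
association
hospital
clinic
clínica
who
unicef
press
media
bot
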