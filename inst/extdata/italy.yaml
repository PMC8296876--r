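macroareas:
- id: Center-North
  strip:
  - Piemonte
  - Emilia Romagna
  - Toscana
  - NITp
  regions:
  - name: Piemonte
    production: 121
    center: Piemonte
  - name: Emilia Romagna
    production: 142
    center: Emilia Romagna
  - name: Toscana
    production: 167
    center: Toscana
  - name: Lombardia
    production: 226
    center: NITp
  - name: Veneto
    production: 130
    center: NITp
  - name: Friuli Venezia Giulia
    production: 0
    center: NITp
  - name: Trentino-Alto Adige
    production: 0
    center: NITp
  - name: Liguria
    production: 0
    center: NITp
  - name: Marche
    production: 0
    center: NITp
  - name: Valle d'Aosta
    production: 0
  - name: Sardegna
    production: 0
- id: Center-South
  strip:
  - Lazio
  - Sicilia
  regions:
  - name: Lazio
    production: 117
    center: Lazio
  - name: Sicilia
    production: 50
    center: Sicilia
  - name: Abruzzo-Molise
    production: 0
  - name: Umbria
    production: 0
  - name: Campania
    production: 0
  - name: Puglia
    production: 0
  - name: Basilicata
    production: 0
  - name: Calabria
    production: 0
centers:
- id: Piemonte
  acceptance_rate: 0.26
  member_regions:
  - Piemonte
- id: Emilia Romagna
  acceptance_rate: 0.26
  member_regions:
  - Emilia Romagna
- id: Toscana
  acceptance_rate: 0.26
  member_regions:
  - Toscana
- id: NITp
  acceptance_rate: 0.26
  member_regions:
  - Friuli Venezia Giulia
  - Liguria
  - Lombardia
  - Marche
  - Trentino-Alto Adige
  - Veneto
- id: Lazio
  acceptance_rate: 0.26
  member_regions:
  - Lazio
- id: Sicilia
  acceptance_rate: 0.26
  member_regions:
  - Sicilia
options:
  head_only_fallback: no
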