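# Added sugar / sweetener lexicon. Terms are matched case-insensitively
# against normalized ingredient text; `juice_patterns` are regular
# expressions applied to the normalized text. Lemon and lime juice are
# excluded from the juice rule by `juice_exclusions`.
schema_version: 1
classes:
  mono_disaccharide:
    - sugar
    - cane sugar
    - brown sugar
    - palm sugar
    - coconut sugar
    - raw sugar
    - icing sugar
    - invert sugar
    - sucrose
    - glucose
    - fructose
    - dextrose
    - lactose
    - maltose
    - galactose
  syrup_nectar_honey:
    - honey
    - molasses
    - agave
    - agave syrup
    - agave nectar
    - maple syrup
    - blossom nectar
    - nectar
    - syrup
    - glucose syrup
    - corn syrup
    - high fructose corn syrup
    - malted barley syrup
    - brown rice syrup
    - rice syrup
    - golden syrup
    - treacle
  nonsugar_sweetener:
    - saccharin
    - acesulfame
    - acesulfame k
    - aspartame
    - sucralose
    - stevia
    - steviol glycosides
    - cyclamate
    - neotame
    - sorbitol
    - xylitol
    - erythritol
    - maltitol
juice_patterns:
  - "\\bjuice\\b"
  - "\\bjuice concentrate\\b"
  - "\\bconcentrated [a-z ]*juice\\b"
  - "\\bpowdered [a-z ]*juice\\b"
  - "\\bjuice powder\\b"
juice_exclusions:
  - lemon
  - lime
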