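# Claim-classification lexicon: regular-expression patterns per claim class,
# applied to normalized claim text. Classes are tried in the order listed
# (most specific first); unmatched text falls through to "other".
schema_version: 1
order:
  - disease_risk_reduction
  - nutrient_function
  - nutrient_content
  - nonpermitted_compositional
patterns:
  disease_risk_reduction:
    - "reduc\\w* (the )?risk"
    - "prevent\\w*"
    - "protects against"
    - "lowers? cholesterol"
  nutrient_function:
    - "(supports?|helps?|aids?|contributes? to|promotes?|for) (healthy )?(growth|development|immun\\w*|bones?|brain|digestion|eyesight|vision)"
    - "(vitamin|iron|calcium|zinc|omega|dha|protein|fibre|fiber|prebiotic|probiotic)[a-z0-9 ]* (supports?|helps?|aids?|contributes? to|promotes?)"
    - "good for (the )?(gut|bones?|brain|immune)"
  nutrient_content:
    - "(high|rich) in [a-z0-9 ]+"
    - "source of [a-z0-9 ]+"
    - "low in [a-z0-9 ]+"
    - "(contains?|with( added)?|provides?|plus) (vitamin|mineral|iron|calcium|zinc|omega|dha|protein|fibre|fiber|wholegrain)[a-z0-9 ]*"
    - "\\b[0-9]+ ?% (of )?(your|daily|rda|rdi)"
  nonpermitted_compositional:
    - "no added [a-z0-9 ]+"
    - "no (artificial|preservative|colour|color|flavour|flavor|sugar|salt)[a-z0-9 ]*"
    - "without (added )?[a-z0-9 ]+"
    - "free (from|of) [a-z0-9 ]+"
    - "[a-z0-9 ]*free$"
    - "naturally occurring"
    - "\\b(100 ?% )?(natural|organic|pure)\\b"
    - "unsweetened"
    - "nothing else added"
    - "just (fruit|vegetables?)[a-z0-9 ]*"
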