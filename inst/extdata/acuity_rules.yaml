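# Reconstructed three-level acuity rule table (BAPM-style categories) over the
# daily-register intervention vocabulary. Rules are evaluated top-down; the
# first match wins; records matching no rule default to special care (SC).
#
# The `pn_no_resp` rule carries both categories: `category` applies under the
# original scheme (parenteral nutrition alone implies intensive care) and
# `adapted_category` replaces it when the adapted scheme is requested
# (parenteral nutrition without any respiratory support implies
# high-dependency care only).
vocabulary:
  - mechanical_respiratory_support
  - invasive_respiratory_support
  - noninvasive_respiratory_support
  - umbilical_line
  - chest_drain
  - parenteral_nutrition
  - phototherapy
  - tube_feeding
rules:
  - id: invasive_support
    category: IC
    any_of: [invasive_respiratory_support, mechanical_respiratory_support]
  - id: chest_drain
    category: IC
    any_of: [chest_drain]
  - id: pn_no_resp
    category: IC
    adapted_category: HDC
    all_of: [parenteral_nutrition]
    none_of: [invasive_respiratory_support, mechanical_respiratory_support,
              noninvasive_respiratory_support]
  - id: noninvasive_support
    category: HDC
    any_of: [noninvasive_respiratory_support]
  - id: umbilical_line
    category: HDC
    any_of: [umbilical_line]
default_category: SC
weights:
  IC: 1.0
  HDC: 0.5
  SC: 0.25
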