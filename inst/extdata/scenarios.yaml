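# Default intervention scenario registry.
#
# Two intervention families on sugar-sweetened beverages:
#   package_cap      - ban/pledge on single-serve packages above `cap` mL
#   energy_reduction - reformulation cutting energy density by `kj_reduction`
#
# Mandatory scenarios assume 100% industry adherence; voluntary scenarios 20%.
# `compensation` is the fraction of capped excess re-consumed in other formats;
# `substitution` the fraction of consumers swapping to a 0 kJ alternative.
scenarios:
  - id: A1
    intervention: package_cap
    cap: 375
    mandatory: true
    adherence: 1.0
    compensation: 0.0
    substitution: 0.0
    description: >-
      Legislated ban on single-serve SSBs above 375 mL, no compensatory
      drinking (base case).
  - id: A2
    intervention: package_cap
    cap: 375
    mandatory: true
    adherence: 1.0
    compensation: 0.25
    substitution: 0.0
    description: Legislated 375 mL cap with 25% compensatory drinking.
  - id: A3
    intervention: package_cap
    cap: 375
    mandatory: true
    adherence: 1.0
    compensation: 0.0
    substitution: 0.10
    description: >-
      Legislated 375 mL cap; 10% of consumers substitute to sugar-free (0 kJ)
      alternatives.
  - id: A4
    intervention: package_cap
    cap: 375
    mandatory: false
    adherence: 0.2
    compensation: 0.0
    substitution: 0.0
    description: Voluntary 375 mL cap pledge, no compensatory drinking.
  - id: A5
    intervention: package_cap
    cap: 375
    mandatory: false
    adherence: 0.2
    compensation: 0.25
    substitution: 0.0
    description: Voluntary 375 mL cap pledge with 25% compensatory drinking.
  - id: A6
    intervention: package_cap
    cap: 375
    mandatory: false
    adherence: 0.2
    compensation: 0.0
    substitution: 0.10
    description: >-
      Voluntary 375 mL cap pledge; 10% of consumers substitute to sugar-free
      alternatives.
  - id: B1
    intervention: energy_reduction
    kj_reduction: 0.05
    mandatory: true
    adherence: 1.0
    description: Legislated 5% energy reduction of all SSBs (base case).
  - id: B2
    intervention: energy_reduction
    kj_reduction: 0.30
    mandatory: true
    adherence: 1.0
    description: Legislated 30% energy reduction of all SSBs.
  - id: B3
    intervention: energy_reduction
    kj_reduction: 0.05
    mandatory: false
    adherence: 0.2
    description: Voluntary 5% energy reduction pledge.
  - id: B4
    intervention: energy_reduction
    kj_reduction: 0.30
    mandatory: false
    adherence: 0.2
    description: Voluntary 30% energy reduction pledge.
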