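# Default anti-CD20 depletion operator: survival fraction per compartment.
# Pro-/pre-B cells do not express the target antigen and are spared; about
# half of immature cells are eliminated; mature circulating, transitional
# and splenic mature pools are fully depleted.
pro_pre: 1.0
immature: 0.5
mature_recirculating: 0.0
transitional: 0.0
splenic_mature: 0.0
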