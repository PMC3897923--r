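u_oa: 0.6
u_oa_bridge: 0.7
u_tka: 0.9
u_rev: 0.85
dis_rev: -0.1
dis_complication: -0.2
p_early_complication: 0.01
p_rev_primary_by_tier:
- 0.005
- 0.01
- 0.02
p_rev_revision_by_tier:
- 0.01
- 0.02
- 0.04
p_mort30_primary: 0.007
p_mort30_revision: 0.01
wait_months: 24.0
c_indirect_oa_annual: 10369.0
c_bridge_annual: 2500.0
c_tka: 26865.0
c_rev: 35542.0
indirect_recovery_fraction: 0.8
bridge_utility_improvement: 0.33
bridge_relief_months: .na.real
discount_annual: 0.03
cohort_age_years: 60.0
scenario: A
max_age_years: 110.0
include_complications: yes
sensitivity:
- parameter: u_oa
  low: 0.4
  high: 0.8
- parameter: u_oa_bridge
  low: 0.6
  high: 0.9
- parameter: u_tka
  low: 0.6
  high: 0.9
- parameter: u_rev
  low: 0.6
  high: 0.9
- parameter: dis_rev
  low: -0.25
  high: 0.0
- parameter: dis_complication
  low: -0.4
  high: 0.0
- parameter: p_early_complication
  low: 0.0
  high: 0.05
- parameter: p_rev_primary_tier1
  low: 0.0
  high: 0.02
- parameter: p_rev_primary_tier2
  low: 0.0
  high: 0.05
- parameter: p_rev_primary_tier3
  low: 0.0
  high: 0.05
- parameter: p_rev_revision_tier1
  low: 0.0
  high: 0.04
- parameter: p_rev_revision_tier2
  low: 0.0
  high: 0.08
- parameter: p_rev_revision_tier3
  low: 0.0
  high: 0.1
- parameter: p_mort30_primary
  low: 0.0
  high: 0.014
- parameter: p_mort30_revision
  low: 0.0
  high: 0.02
- parameter: wait_months
  low: 0.75
  high: 60.0
- parameter: c_indirect_oa_annual
  low: 0.0
  high: 20000.0
- parameter: c_bridge_annual
  low: 0.0
  high: 3883.0
- parameter: c_tka
  low: 20000.0
  high: 30000.0
- parameter: c_rev
  low: 30000.0
  high: 40000.0
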