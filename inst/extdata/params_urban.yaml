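# Model parameters, urban setting. Clinical values (base, lo, hi = 95% CI)
# and cost line items transcribed from the published parameter and costing
# tables; compliance and the background mortality schedule are synthetic
# defaults (the source study does not print them) and are documented as
# assumptions, not published values.
setting: urban
prevalence:
  npdr: {base: 0.149, lo: 0.106, hi: 0.204}
  pdr:  {base: 0.011, lo: 0.005, hi: 0.023}
  dme:  {base: 0.026, lo: 0.023, hi: 0.029}
transitions:
  normal_to_npdr:     {base: 0.0328, lo: 0.0184, hi: 0.0578}
  normal_to_pdr:      {base: 0.0024, lo: 0.0009, hi: 0.0063}
  npdr_to_pdr:        {base: 0.0106, lo: 0.0040, hi: 0.0278}
  npdr_to_dme:        {base: 0.0107, lo: 0.0096, hi: 0.0118}
  pdr_to_dme:         {base: 0.0290, lo: 0.0261, hi: 0.0319}
  pdr_to_svi:         {base: 0.0278, lo: 0.0100, hi: 0.0744}
  dme_to_svi:         {base: 0.0500, lo: 0.0450, hi: 0.0550}
  treated_pdr_to_svi: {base: 0.0116, lo: 0.0005, hi: 0.0268}
  treated_dme_to_svi: {base: 0.0300, lo: 0.0270, hi: 0.0330}
utilities:
  no_dr: {base: 0.95, lo: 0.92, hi: 0.99}
  npdr:  {base: 0.79, lo: 0.71, hi: 0.87}
  pdr:   {base: 0.70, lo: 0.63, hi: 0.77}
  dme:   {base: 0.70, lo: 0.63, hi: 0.77}
  svi:   {base: 0.55, lo: 0.50, hi: 0.61}
tests:
  community:
    normal_called_npdr:   {base: 0.05, lo: 0.04, hi: 0.06}
    normal_called_normal: {base: 0.95, lo: 0.86, hi: 1.00}
    npdr_called_normal:   {base: 0.22, lo: 0.20, hi: 0.24}
    pdr_called_npdr:      {base: 0.03, lo: 0.02, hi: 0.04}
    pdr_called_normal:    {base: 0.02, lo: 0.01, hi: 0.03}
    dme_sensitivity:      {base: 0.82, lo: 0.74, hi: 0.90}
    dme_specificity:      {base: 0.79, lo: 0.71, hi: 0.87}
  telemedicine:
    normal_called_npdr:   {base: 0.04, lo: 0.03, hi: 0.05}
    normal_called_normal: {base: 0.96, lo: 0.86, hi: 1.00}
    npdr_called_normal:   {base: 0.42, lo: 0.38, hi: 0.46}
    pdr_called_npdr:      {base: 0.19, lo: 0.17, hi: 0.21}
    pdr_called_normal:    {base: 0.02, lo: 0.01, hi: 0.03}
    dme_sensitivity:      {base: 0.80, lo: 0.72, hi: 0.88}
    dme_specificity:      {base: 0.95, lo: 0.86, hi: 1.00}
costs:
  currency: USD
  screening_items:
    community:
      - {item: "Nonmydriatic retinal camera", kind: capital, units: 1, unit_cost: 24000, life_years: 5}
      - {item: "Visual acuity chart", kind: capital, units: 1, unit_cost: 250, life_years: 5}
      - {item: "Laptop", kind: capital, units: 1, unit_cost: 500, life_years: 5}
      - {item: "Medical staff", kind: recurring, units: 6, annual_cost: 39000}
      - {item: "Posters, leaflets and loose expenses", kind: recurring, annual_cost: 700}
      - {item: "Casual supporting personnel", kind: recurring, annual_cost: 640}
      - {item: "Transportation", kind: recurring, annual_cost: 3000}
    telemedicine:
      - {item: "Computer software and peripherals", kind: capital, units: 1, unit_cost: 9000, life_years: 5}
      - {item: "Installation", kind: capital, units: 1, unit_cost: 5000, life_years: 5}
      - {item: "Contract cost to other organizations", kind: recurring, annual_cost: 1700}
      - {item: "Medical staff, specialists", kind: recurring, units: 10, annual_cost: 25000}
      - {item: "Medical staff, technicians", kind: recurring, units: 2, annual_cost: 5000}
      - {item: "Maintenance", kind: recurring, annual_cost: 2000}
  hospital_exam_items:
    - {item: "Medical service", cost: 8.48}
    - {item: "Fundus photography", cost: 4.74}
    - {item: "Optical coherence tomography", cost: 13.85}
    - {item: "Visual acuity and noncontact IOP measurement", cost: 0.78}
    - {item: "Transportation and accommodation", cost: 63.76}
    - {item: "Internal medical examination", cost: 8.39}
  photocoagulation: 137.60
  anti_vegf: 1741.46
  followup_maintain: 122.32
  svi_first_year: 8800
  svi_subsequent_year: 3600
mortality:
  rr_diabetes: {base: 1.97}
  rr_svi: {base: 3.9}
  svi_multiplier_mode: replace
  life_table:
    gompertz: {a: 0.004, b: 0.085}
    age_from: 50
    age_to: 100
compliance:
  # synthetic defaults (assumption; the source cites unpublished data)
  uptake: {base: 0.80}
  referral_acceptance: {base: 0.70}
economics:
  discount_rate: 0.035
  n_cycles: 30
  cycle_length: 1
  start_age: 50
  persons_screened_per_year: 20000
  exchange_rate_cny_per_usd: 6.9762
  wtp_1x: 12000
dsa_ranges:
  probability: 0.10
  utility: 0.10
  test: 0.10
  compliance: 0.10
  cost_program: 0.20
  cost_treatment: 0.50
model_options:
  treated_pdr_to_dme: false
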