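# Synthetic placeholder taxonomy.
# Category names follow published summary tables of the public-health
# social-listening taxonomy; the production keyword appendices are not
# public, so every keyword list below is a documented placeholder chosen
# for shape, not fidelity. Supply your own config of the same layout for
# real analyses.
version: "placeholder-1"
categories:
  - id: cause_of_virus
    name: The Cause of the Virus
    topic: cause
    keywords:
      en: [virus origin, lab leak, patient zero, animal market]
      es: [origen del virus, paciente cero]
  - id: modes_of_transmission
    name: Modes of Transmission
    topic: cause
    keywords:
      en: [airborne, droplets, aerosol, surface transmission]
  - id: transmission_settings
    name: Transmission Settings
    topic: cause
    keywords:
      en: [school outbreak, workplace outbreak, crowded indoor, public transport]
  - id: statistics_data
    name: Statistics & Data
    topic: information
    keywords:
      en: [case numbers, death toll, positivity rate, daily cases]
  - id: myths
    name: Myths
    topic: information
    keywords:
      en: [hoax, conspiracy, microchip, fake pandemic]
  - id: faith
    name: Faith
    topic: information
    keywords:
      en: [prayer, god, church service, faith healing]
  - id: stigma_spread
    name: Stigma around the Spread
    topic: information
    keywords:
      en: [blame, stigma, discrimination, scapegoat]
  - id: civil_unrest
    name: Civil Unrest
    topic: information
    keywords:
      en: [protest, riot, lockdown protest, unrest]
  - id: other_symptoms
    name: Other Discussed Symptoms
    topic: illness
    keywords:
      en: [sore throat, loss of smell, fatigue, ear ache]
  - id: immunity
    name: Immunity
    topic: illness
    keywords:
      en: [antibodies, herd immunity, natural immunity, immune response]
  - id: youth
    name: Youth
    topic: illness
    keywords:
      en: [children, teenagers, schools reopening, young people]
  - id: pandemic_fatigue
    name: Pandemic Fatigue
    topic: illness
    keywords:
      en: [tired of lockdown, fed up, pandemic fatigue, burnout]
  - id: current_treatments
    name: Current Treatments
    topic: treatment
    keywords:
      en: [antiviral, dexamethasone, treatment protocol, oxygen therapy]
  - id: supportive_care
    name: Supportive Care
    topic: treatment
    keywords:
      en: [home care, rest and fluids, recovery tips, caring for patient]
  - id: health_technology
    name: Health Technology
    topic: treatment
    keywords:
      en: [ventilator, oximeter, medical device, diagnostics]
  - id: digital_health_technology
    name: Digital Health Technology
    topic: treatment
    keywords:
      en: [contact tracing app, health app, telemedicine, digital certificate]
  - id: testing
    name: Testing
    topic: interventions
    keywords:
      en: [pcr test, rapid test, testing centre, swab]
  - id: measures_public_settings
    name: Measures in Public Settings
    topic: interventions
    keywords:
      en: [mask mandate, social distancing, curfew, capacity limit]
  - id: reduction_domestic_movement
    name: Reduction of Domestic Movement
    topic: interventions
    keywords:
      en: [travel ban, stay at home, movement restriction, quarantine rules]
  - id: general_vaccine_discussion
    name: General Vaccine Discussion
    topic: interventions
    keywords:
      en: [vaccine, vaccination, jab, booster]
  - id: vaccine_distribution_access
    name: Vaccine Distribution and Policies on Access
    topic: interventions
    keywords:
      en: [vaccine rollout, vaccine appointment, dose supply, priority groups]
  - id: hcw_vaccine
    name: Health Care Workers & Vaccine
    topic: interventions
    keywords:
      en: [nurse vaccination, doctor vaccinated, frontline workers vaccine, staff mandate]
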