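# Packaged 36-feature schema for the T2DM national-health-survey table:
# 4 continuous, 25 ordinal, 7 nominal features in five qualitative categories.
# Ordinal level order is rank order (first = lowest).
features:
  # --- comorbidity (6, binary ordinal) ---
  - name: asthma
    type: ordinal
    levels: ["No", "Yes"]
    category: comorbidity
  - name: thyroid_disorder
    type: ordinal
    levels: ["No", "Yes"]
    category: comorbidity
  - name: heart_disease
    type: ordinal
    levels: ["No", "Yes"]
    category: comorbidity
  - name: cancer
    type: ordinal
    levels: ["No", "Yes"]
    category: comorbidity
  - name: tuberculosis
    type: ordinal
    levels: ["No", "Yes"]
    category: comorbidity
  - name: hypertension
    type: ordinal
    levels: ["No", "Yes"]
    category: comorbidity
  # --- food habits (9, four-level frequency ordinal) ---
  - name: milk_curd_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: pulses_beans_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: green_vegetables_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: fruit_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: egg_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: fish_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: chicken_meat_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: fried_food_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  - name: aerated_drink_freq
    type: ordinal
    levels: [Never, Weekly, Occasionally, Daily]
    category: food
  # --- addiction history (2, binary ordinal) ---
  - name: smoker
    type: ordinal
    levels: ["No", "Yes"]
    category: addiction
  - name: alcohol
    type: ordinal
    levels: ["No", "Yes"]
    category: addiction
  # --- socio-demographic (8: 3 continuous, 3 nominal, 2 ordinal) ---
  - name: age
    type: continuous
    category: sociodemographic
  - name: bmi
    type: continuous
    category: sociodemographic
  - name: haemoglobin
    type: continuous
    category: sociodemographic
  - name: sex
    type: nominal
    levels: [Male, Female]
    category: sociodemographic
  - name: wealth_index
    type: ordinal
    levels: [Poorest, Poorer, Middle, Richer, Richest]
    category: sociodemographic
  - name: education_level
    type: ordinal
    levels: [No education, Primary level, Secondary level, Higher level]
    category: sociodemographic
  - name: religion
    type: nominal
    levels: [Hindu, Muslim, Christian, Others]
    category: sociodemographic
  - name: caste
    type: nominal
    levels: [OBC, SC, ST, General]
    category: sociodemographic
  # --- living conditions (11: 1 continuous, 4 nominal, 6 ordinal) ---
  - name: refrigerator
    type: ordinal
    levels: ["No", "Yes"]
    category: living
  - name: bicycle
    type: ordinal
    levels: ["No", "Yes"]
    category: living
  - name: motorbike
    type: ordinal
    levels: ["No", "Yes"]
    category: living
  - name: car_truck
    type: ordinal
    levels: ["No", "Yes"]
    category: living
  - name: livestock
    type: ordinal
    levels: ["No", "Yes"]
    category: living
  # intensity order, not table row order
  - name: indoor_smoking_freq
    type: ordinal
    levels: [Never, Less than monthly, Monthly, Weekly, Daily]
    category: living
  - name: residence
    type: nominal
    levels: [Urban, Rural]
    category: living
  - name: household_structure
    type: nominal
    levels: [Non-nuclear, Nuclear]
    category: living
  - name: cooking_fuel
    type: nominal
    levels: [Other, Plant based, Livestock based, Gas/oil, Electricity]
    category: living
  - name: water_source
    type: nominal
    levels: [Unprotected sources, Protected sources, Community service,
             Bottled water, Other]
    category: living
  - name: time_to_water_source
    type: continuous
    category: living
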