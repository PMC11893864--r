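# Heart-disease tabular schema, standard UCI/Kaggle coding.
# 13 predictors: 5 numeric, 8 nominal; binary target (1 = heart disease).
version: 1
target:
  name: target
  kind: nominal
  codes: [0, 1]
predictors:
  - name: age
    kind: numeric
    range: [18, 100]        # years
  - name: sex
    kind: nominal
    codes: [0, 1]
  - name: cp                # chest pain type: 0 typical angina .. 3 asymptomatic
    kind: nominal
    codes: [0, 1, 2, 3]
  - name: trestbps          # resting blood pressure, mm Hg
    kind: numeric
    range: [60, 250]
  - name: chol              # serum cholesterol, mg/dl
    kind: numeric
    range: [80, 700]
  - name: fbs               # fasting blood sugar > 120 mg/dl
    kind: nominal
    codes: [0, 1]
  - name: restecg           # resting ECG result
    kind: nominal
    codes: [0, 1, 2]
  - name: thalach           # maximum heart rate achieved, bpm
    kind: numeric
    range: [50, 250]
  - name: exang             # exercise-induced angina
    kind: nominal
    codes: [0, 1]
  - name: oldpeak           # exercise-induced ST depression
    kind: numeric
    range: [0, 10]
  - name: slope             # slope of the peak-exercise ST segment
    kind: nominal
    codes: [0, 1, 2]
  - name: ca                # number of major vessels colored by fluoroscopy
    kind: nominal
    codes: [0, 1, 2, 3]
  - name: thal              # thalassemia status; 0 is a recorded-as-missing code
    kind: nominal
    codes: [0, 1, 2, 3]
missing_codes:
  thal: [0]
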