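# Condition bands classifying each symptom (HDP) value as pathological-high (a),
# pathological-low (b) or normal (c). Anthropometric bounds are arithmetic
# expressions over Wt (weight, kg), L (height, cm) and Q (body-size factor).
# The AC row defines only band a: its normal band is not usable as published
# (the printed c bound duplicates the a bound) and is deliberately left absent.
symptoms:
  SP:
    a: {op: ge, value: 160}
    b: {op: lt, value: 90}
    c: {op: range, lower: 110, upper: 130}
  DP:
    a: {op: ge, value: 95}
    c: {op: range, lower: 80, upper: 90}
  MAP:
    a: {op: gt, value: 115}
    b: {op: lt, value: 65}
    c: {op: range, lower: 70, upper: 100}
  MDP:
    a: {op: gt, value: 105}
    c: {op: range, lower: 66, upper: 96}
  BV:
    a: {op: le, expr: "0.75 * Wt * 0.075"}
    c: {op: range, lower_expr: "0.75 * Wt * 0.075", upper_expr: "1.25 * Wt * 0.075"}
  PR:
    a: {op: ge, value: 104}
    b: {op: lt, value: 50}
    c: {op: range, lower: 60, upper: 100}
  Wt:
    a: {op: gt, value: 20}
    c: {op: range, lower: 50, upper: 80}
  SV:
    a: {op: le, expr: "0.8 * (1 + Q) * 20 * Q"}
    b: {op: ge, expr: "1.3 * 1.2 * (1 + Q) * 20 * Q"}
    c: {op: approx, expr: "(1 + Q) * 20 * Q"}
  SI:
    a: {op: le, expr: "0.8 * (1 + Q) * 20"}
    b: {op: ge, expr: "1.3 * 1.2 * (1 + Q) * 20"}
    c: {op: approx, expr: "(1 + Q) * 20"}
  VPE:
    a: {op: le, expr: "0.8 * 2 * (Wt + 45) * 0.0112"}
    b: {op: ge, expr: "1.2 * 2 * (Wt + 45) * 0.0112"}
    c: {op: approx, expr: "(2 * Wt + 45) * 0.0112"}
  CI:
    a: {op: ge, value: 2.2}
    c: {op: range, lower_expr: "(1 + Q) * 1.2", upper_expr: "(1 + Q) * 2"}
  "Y":
    a: {op: ge, expr: "1.1 * 4"}
    b: {op: le, expr: "0.85 * 3"}
    c: {op: range, lower: 3, upper: 4}
  "Yr":
    a: {op: ge, expr: "1.1 * 4"}
    b: {op: le, expr: "0.85 * 3"}
    c: {op: range, lower: 3, upper: 4}
  AC:
    a: {op: ge, value: 1.2}
  FEK:
    a: {op: ge, expr: "0.9 * 0.25"}
    c: {op: range, lower: 0.35, upper: 0.55}
  BLK:
    a: {op: lt, expr: "0.85 * 0.22"}
    c: {op: range, lower: 0.22, upper: 0.26}
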