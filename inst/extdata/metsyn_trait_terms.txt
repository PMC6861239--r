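metabolic syndrome
obesity
abdominal obesity
hyperglycemia
insulin resistance
hyperinsulinism
glucose intolerance
type 2 diabetes
hypertension
hypertriglyceridemia
high triglycerides
hypercholesterolemia
low hdl cholesterol
waist circumference
waist-hip ratio
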