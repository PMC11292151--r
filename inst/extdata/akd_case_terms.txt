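# Acute kidney disease case definition: MedDRA-style preferred terms.
# A report is a case when any of its reaction terms matches one of these
# (case- and whitespace-insensitive).
acute kidney injury
renal failure
renal impairment
blood creatinine increased
renal injury
blood urea increased
tubulointerstitial nephritis
glomerular filtration rate decreased
oliguria
anuria
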