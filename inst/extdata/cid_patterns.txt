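# Default sentence-level CID trigger patterns, one template per line.
# CHEMICAL and DISEASE (or SE) mark the annotated entity slots.
CHEMICAL-induced DISEASE
CHEMICAL-associated DISEASE
DISEASE caused by CHEMICAL
DISEASE during CHEMICAL
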