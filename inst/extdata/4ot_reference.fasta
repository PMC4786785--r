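>4OT_reference 4-oxalocrotonate tautomerase, Pseudomonas putida mt-2, mature chain (Pro-1..Arg-62)
PIAQIHILEGRSDEQKETLIREVSEAISRSLDAPLTSVRVIITEMAKGHFGIAGELASKVRR
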