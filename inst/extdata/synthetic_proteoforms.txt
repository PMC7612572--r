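# Synthetic demonstration pair: the same N-terminal protein segment as an
# unmodified proteoform and as a modified proteoform carrying an
# unlocalized phosphorylation, an N-terminal acetylation and a 174.3 Da
# mass shift on an arginine.  The sequence itself is invented for
# demonstration purposes.
MDPEVRLAKSQES
[Phospho]?[Acetyl]-MDPEVR[+174.3]LAKSQES
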