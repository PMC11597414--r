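>TAS synthetic stand-in for the termination-associated sequence element
TACATAATTGATTAT
>CSB1 synthetic stand-in for conserved sequence block 1
TTAAACATAACAAATTAATGAACGT
>mTF1 synthetic stand-in for a transcription-factor binding site
AACATAGCACATTACAGT
>mt3 synthetic stand-in for a transcription-factor binding site
TGGCAGAGATGTGT
>mt4 synthetic stand-in for a transcription-factor binding site
CACAGGTCTATCAC
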