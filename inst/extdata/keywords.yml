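# Default keyword configuration: the 13 search patterns used to flag
# wild-pig mentions in threat narratives. Wildcard entries match any
# letter suffix of the token.
literals:
  - pig
  - pigs
  - domesticus
  - sus
  - scrofa
  - boar
  - boars
  - hog
  - hogs
  - swine
prefixes:
  - "pig*"
  - "boar*"
  - "hog*"
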