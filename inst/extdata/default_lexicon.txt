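# Default sentiment lexicon for patient-review mining.
# 30 polarity-labelled seed adjectives plus a synonym/antonym neighbourhood
# (symmetrized on load). Synonyms share polarity; antonyms flip it.

[seeds]
good	positive
great	positive
excellent	positive
effective	positive
helpful	positive
comfortable	positive
gentle	positive
successful	positive
safe	positive
reassuring	positive
pleasant	positive
quick	positive
caring	positive
thorough	positive
manageable	positive
bad	negative
terrible	negative
awful	negative
painful	negative
severe	negative
harmful	negative
uncomfortable	negative
distressing	negative
risky	negative
slow	negative
careless	negative
ineffective	negative
unpleasant	negative
extreme	negative
frightening	negative

[synonyms]
excruciating: painful, unbearable
unbearable: intolerable
agonizing: excruciating
sore: painful
radical: extreme, drastic
drastic: extreme
harsh: severe
brutal: harsh, severe
scary: frightening
terrifying: frightening
horrible: terrible, awful
dreadful: terrible
fine: good
nice: pleasant
wonderful: great, excellent
soothing: comfortable, reassuring
swift: quick
rapid: quick
mild: gentle
beneficial: helpful
efficient: effective
tolerable: manageable
stressful: distressing
worrying: distressing
dangerous: risky
compassionate: caring

[antonyms]
good: bad
painful: painless
comfortable: uncomfortable
safe: risky
gentle: rough
effective: ineffective
pleasant: unpleasant
quick: slow
careful: careless
reassuring: alarming
helpful: harmful
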