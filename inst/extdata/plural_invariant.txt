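# Words returned unchanged by singularization: either identical in singular
# and plural, or singulars whose endings look plural. One word per line.
sheep
fish
deer
moose
swine
bison
salmon
trout
species
series
offspring
semen
mucus
pus
vas
gas
pancreas
atlas
alias
bias
canvas
lens
news
measles
rabies
scabies
herpes
diabetes
caries
facies
feces
forceps
biceps
triceps
meninges
scissors
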