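# Irregular English plural -> singular pairs, one pair per line.
# Biomedical Latin/Greek plurals are included because ontology labels use them.
children child
feet foot
teeth tooth
geese goose
mice mouse
lice louse
men man
women woman
oxen ox
people person
criteria criterion
phenomena phenomenon
bacteria bacterium
mitochondria mitochondrion
ganglia ganglion
data datum
media medium
genera genus
corpora corpus
viscera viscus
vertebrae vertebra
larvae larva
antennae antenna
fistulae fistula
maxillae maxilla
scapulae scapula
conjunctivae conjunctiva
aortae aorta
vaginae vagina
nuclei nucleus
fungi fungus
stimuli stimulus
foci focus
villi villus
nevi nevus
bronchi bronchus
alveoli alveolus
glomeruli glomerulus
emboli embolus
thrombi thrombus
calculi calculus
radii radius
analyses analysis
diagnoses diagnosis
prognoses prognosis
hypotheses hypothesis
neuroses neurosis
stenoses stenosis
testes testis
pelves pelvis
septa septum
ova ovum
cilia cilium
flagella flagellum
cerebella cerebellum
epithelia epithelium
endothelia endothelium
ostia ostium
atria atrium
crania cranium
ilia ilium
labia labium
matrices matrix
indices index
appendices appendix
cortices cortex
vortices vortex
apices apex
vasa vas
leaves leaf
loaves loaf
wolves wolf
calves calf
halves half
shelves shelf
scarves scarf
hooves hoof
knives knife
wives wife
lives life
gases gas
irises iris
potatoes potato
heroes hero
echoes echo
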