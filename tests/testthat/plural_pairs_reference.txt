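# Reference English plural/singular pairs: plural singular, one pair per line.
ears ear
eyes eye
glands gland
bones bone
lobes lobe
cells cell
hearts heart
lungs lung
kidneys kidney
livers liver
muscles muscle
nerves nerve
veins vein
tendons tendon
ligaments ligament
neurons neuron
organs organ
tissues tissue
membranes membrane
follicles follicle
tubules tubule
valves valve
chambers chamber
vessels vessel
fibers fiber
joints joint
limbs limb
fingers finger
toes toe
nails nail
hairs hair
genes gene
proteins protein
enzymes enzyme
receptors receptor
hormones hormone
molecules molecule
signals signal
pathways pathway
diseases disease
syndromes syndrome
disorders disorder
phenotypes phenotype
structures structure
functions function
secretions secretion
mutations mutation
deletions deletion
duplications duplication
inversions inversion
chromosomes chromosome
nucleotides nucleotide
ribosomes ribosome
lysosomes lysosome
vesicles vesicle
axons axon
dendrites dendrite
synapses synapse
impulses impulse
responses response
lesions lesion
tumors tumor
cysts cyst
polyps polyp
ulcers ulcer
wounds wound
scars scar
fractures fracture
infections infection
cases case
houses house
phrases phrase
membranes membrane
glucagons glucagon
bodies body
arteries artery
ovaries ovary
capillaries capillary
studies study
anomalies anomaly
deformities deformity
extremities extremity
cavities cavity
deficiencies deficiency
categories category
properties property
qualities quality
activities activity
abilities ability
injuries injury
allergies allergy
therapies therapy
biopsies biopsy
colonies colony
antibodies antibody
families family
arteries artery
processes process
crosses cross
masses mass
classes class
illnesses illness
weaknesses weakness
boxes box
reflexes reflex
complexes complex
suffixes suffix
branches branch
patches patch
matches match
switches switch
arches arch
rashes rash
flashes flash
brushes brush
wishes wish
buzzes buzz
viruses virus
fetuses fetus
sinuses sinus
boluses bolus
calluses callus
uteruses uterus
anuses anus
statuses status
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
sheep sheep
fish fish
deer deer
moose moose
swine swine
species species
series series
offspring offspring
semen semen
pancreas pancreas
forceps forceps
biceps biceps
feces feces
diabetes diabetes
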