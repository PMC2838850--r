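# Filler vocabulary for the synthetic record-corpus generator.
# One token per line; generic biomedical narrative words.
protein
gene
cell
receptor
kinase
enzyme
pathway
signal
membrane
nucleus
cytoplasm
chromosome
mutation
variant
allele
expression
transcription
translation
regulation
binding
domain
sequence
structure
function
activity
complex
subunit
isoform
promoter
enhancer
intron
exon
codon
peptide
ligand
substrate
inhibitor
activator
phosphorylation
methylation
acetylation
ubiquitin
degradation
synthesis
secretion
transport
channel
pump
gradient
homolog
ortholog
paralog
family
motif
residue
terminal
cascade
feedback
loop
induction
repression
silencing
knockout
transgenic
phenotype
genotype
locus
linkage
marker
polymorphism
haplotype
recombination
segregation
inheritance
dominant
recessive
autosomal
deficiency
disorder
syndrome
disease
patient
clinical
diagnosis
prognosis
therapy
treatment
drug
dose
response
resistance
susceptibility
severity
onset
progression
remission
relapse
chronic
acute
systemic
localized
tissue
organ
muscle
bone
cartilage
synovium
epithelium
endothelium
fibroblast
macrophage
lymphocyte
monocyte
neutrophil
granulocyte
platelet
erythrocyte
plasma
serum
antibody
antigen
epitope
cytokine
chemokine
interleukin
interferon
necrosis
apoptosis
proliferation
differentiation
migration
adhesion
invasion
angiogenesis
vascular
arterial
venous
capillary
cardiac
hepatic
renal
pulmonary
neural
cortical
spinal
peripheral
central
sensory
motor
reflex
stimulus
threshold
potential
current
voltage
calcium
sodium
potassium
chloride
zinc
iron
copper
magnesium
glucose
lipid
cholesterol
fatty
amino
nucleotide
purine
pyrimidine
ribosome
mitochondria
lysosome
peroxisome
golgi
reticulum
vesicle
endosome
autophagy
oxidative
stress
radical
peroxide
antioxidant
metabolism
catabolism
anabolism
glycolysis
respiration
fermentation
homeostasis
equilibrium
balance
concentration
diffusion
osmosis
permeability
barrier
junction
gap
tight
desmosome
integrin
cadherin
selectin
collagen
elastin
fibronectin
laminin
matrix
scaffold
fiber
filament
tubule
actin
myosin
tubulin
keratin
spindle
centromere
telomere
replication
repair
excision
mismatch
ligase
polymerase
helicase
nuclease
protease
lipase
oxidase
reductase
transferase
hydrolase
isomerase
synthase
carrier
transporter
exchanger
symporter
uptake
efflux
clearance
absorption
distribution
elimination
excretion
filtration
reabsorption
glomerular
tubular
cortex
medulla
gland
hormone
insulin
glucagon
cortisol
thyroid
pituitary
adrenal
pancreas
hepatocyte
neuron
astrocyte
microglia
oligodendrocyte
myelin
axon
dendrite
synapse
vesicular
neurotransmitter
dopamine
serotonin
glutamate
glycine
histamine
bradykinin
prostaglandin
leukotriene
thromboxane
eicosanoid
steroid
retinoid
vitamin
cofactor
coenzyme
heme
porphyrin
globin
albumin
globulin
fibrinogen
thrombin
plasmin
coagulation
fibrinolysis
hemostasis
hemorrhage
thrombosis
embolism
infarction
ischemia
hypoxia
perfusion
reperfusion
edema
effusion
exudate
infiltrate
lesion
nodule
plaque
erosion
ulcer
fibrosis
sclerosis
atrophy
hypertrophy
hyperplasia
dysplasia
metaplasia
neoplasia
carcinoma
sarcoma
lymphoma
leukemia
melanoma
adenoma
papilloma
benign
malignant
metastasis
invasive
screening
biopsy
histology
cytology
staining
imaging
resonance
tomography
ultrasound
radiograph
scintigraphy
assay
titer
dilution
incubation
centrifugation
electrophoresis
chromatography
spectrometry
sequencing
amplification
hybridization
cloning
vector
plasmid
library
probe
primer
template
fragment
digestion
restriction
insertion
deletion
duplication
inversion
translocation
aneuploidy
trisomy
monosomy
mosaicism
imprinting
epigenetic
heritability
penetrance
expressivity
pleiotropy
epistasis
modifier
background
strain
inbred
outbred
congenic
backcross
intercross
pedigree
cohort
population
sample
frequency
prevalence
incidence
mortality
morbidity
risk
odds
hazard
exposure
confounder
association
correlation
regression
variance
deviation
significance
hypothesis
model
parameter
estimate
interval
distribution
random
uniform
normal
skewed
outlier
replicate
control
baseline
placebo
blinded
randomized
longitudinal
transverse
prospective
retrospective
observational
experimental
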