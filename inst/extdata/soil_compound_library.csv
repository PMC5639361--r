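name,formula,monoisotopic_mass,met_class,plausible_in_soil
HBOA,C8H7NO3,,benzoxazinoid,TRUE
DIBOA,C8H7NO4,,benzoxazinoid,TRUE
HMBOA,C9H9NO4,,benzoxazinoid,TRUE
DIMBOA,C9H9NO5,,benzoxazinoid,TRUE
MBOA,C8H7NO3,,benzoxazinoid,TRUE
quercetin,C15H10O7,,flavonoid,TRUE
kaempferol,C15H10O6,,flavonoid,TRUE
apigenin,C15H10O5,,flavonoid,TRUE
naringenin,C15H12O5,,flavonoid,TRUE
catechin,C15H14O6,,flavonoid,TRUE
rutin,C27H30O16,,flavonoid,TRUE
luteolin,C15H10O6,,flavonoid,TRUE
ferulic acid,C10H10O4,,phenylpropanoid,TRUE
caffeic acid,C9H8O4,,phenylpropanoid,TRUE
p-coumaric acid,C9H8O3,,phenylpropanoid,TRUE
chlorogenic acid,C16H18O9,,phenylpropanoid,TRUE
cinnamic acid,C9H8O2,,phenylpropanoid,TRUE
palmitic acid,C16H32O2,,lipid,TRUE
linoleic acid,C18H32O2,,lipid,TRUE
oleic acid,C18H34O2,,lipid,TRUE
stearic acid,C18H36O2,,lipid,TRUE
lysophosphatidylcholine 16:0,C24H50NO7P,,lipid,TRUE
trigonelline,C7H7NO2,,alkaloid,TRUE
gramine,C11H14N2,,alkaloid,TRUE
nicotine,C10H14N2,,alkaloid,TRUE
citric acid,C6H8O7,,organic acid,TRUE
malic acid,C4H6O5,,organic acid,TRUE
succinic acid,C4H6O4,,organic acid,TRUE
fumaric acid,C4H4O4,,organic acid,TRUE
tryptophan,C11H12N2O2,,amino acid,TRUE
phenylalanine,C9H11NO2,,amino acid,TRUE
glutamine,C5H10N2O3,,amino acid,TRUE
proline,C5H9NO2,,amino acid,TRUE
glucose,C6H12O6,,sugar,TRUE
sucrose,C12H22O11,,sugar,TRUE
salicylic acid,C7H6O3,,miscellaneous,TRUE
indole-3-acetic acid,C10H9NO2,,miscellaneous,TRUE
scopoletin,C10H8O4,,miscellaneous,TRUE
ibuprofen,C13H18O2,,synthetic drug,FALSE
diazepam,C16H13ClN2O,,synthetic drug,FALSE
paracetamol,C8H9NO2,,synthetic drug,FALSE
testosterone,C19H28O2,,mammalian hormone,FALSE
estradiol,C18H24O2,,mammalian hormone,FALSE
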