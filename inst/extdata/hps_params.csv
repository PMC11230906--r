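# Per-type parameters of the hydrophobicity-scale implicit-solvent model
# (one bead per residue). sigma: van der Waals diameter (Angstrom); lambda:
# normalized hydrophobicity in [0,1]; mass: residue mass (Dalton); charge:
# unit charges. K and E values are the published hydrophobicity-scale
# parameters for lysine and glutamate. CORE is the star scaffold bead:
# neutral, purely repulsive (is_core = 1 forces pair lambda to 0), diameter
# twice the lysine bead, mass scaled with its volume.
type,sigma,lambda,mass,charge,is_core
K,6.36,0.514,128.174,1,0
E,5.92,0.459,129.115,-1,0
CORE,12.72,0,1025.4,0,1
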