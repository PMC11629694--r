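HBA1
HBA2
HBD
logP
MR
TPSA
nF
HeavyAtomCount
TotalHCount
NumRingBonds
NumRingAtoms
CyclomaticNumber
NumComponents
FormalChargeSum
NumPosCharged
NumNegCharged
NumAromaticAtoms
FractionAromatic
FractionCSP3
NumRotatableBonds
MeanDegree
MaxDegree
GraphDiameter
WienerIndex
MeanAtomicMass
MolWt
NumHeteroatoms
TerminalAtomCount
BranchAtomCount
Count_C
Count_N
Count_O
Count_S
Count_P
Count_F
Count_Cl
Count_Br
Count_I
Count_B
Count_Si
Count_Se
Count_Na
Count_K
Count_Li
Count_Mg
Count_Ca
Count_Zn
Count_Fe
Count_other
DegreeCount_0
DegreeCount_1
DegreeCount_2
DegreeCount_3
DegreeCount_4
DegreeCount_5
DegreeCount_6
HCount_0
HCount_1
HCount_2
HCount_3
HCount_4
HybridCount_SP
HybridCount_SP2
HybridCount_SP3
HybridCount_SP3D
HybridCount_SP3D2
BondCount_single
BondCount_double
BondCount_triple
BondCount_aromatic
BondCount_amide
PairCount_C_C
PairCount_C_N
PairCount_C_O
PairCount_C_S
PairCount_C_P
PairCount_N_O
PairCount_N_N
PairCount_N_P
PairCount_O_P
PairCount_O_S
PairCount_C_X
PairCount_other_pair
AdjEig1
AdjEig2
AdjEig3
LaplacianEig2
ATS1_mass
ATS2_mass
ATS3_mass
ATS4_mass
ATS5_mass
ATS1_charge
ATS2_charge
ATS3_charge
ATS4_charge
ATS5_charge
ATS1_en
ATS2_en
ATS3_en
ATS4_en
ATS5_en
EnvHash1_000
EnvHash1_001
EnvHash1_002
EnvHash1_003
EnvHash1_004
EnvHash1_005
EnvHash1_006
EnvHash1_007
EnvHash1_008
EnvHash1_009
EnvHash1_010
EnvHash1_011
EnvHash1_012
EnvHash1_013
EnvHash1_014
EnvHash1_015
EnvHash1_016
EnvHash1_017
EnvHash1_018
EnvHash1_019
EnvHash1_020
EnvHash1_021
EnvHash1_022
EnvHash1_023
EnvHash1_024
EnvHash1_025
EnvHash1_026
EnvHash1_027
EnvHash1_028
EnvHash1_029
EnvHash1_030
EnvHash1_031
EnvHash1_032
EnvHash1_033
EnvHash1_034
EnvHash1_035
EnvHash1_036
EnvHash1_037
EnvHash1_038
EnvHash1_039
EnvHash1_040
EnvHash1_041
EnvHash1_042
EnvHash1_043
EnvHash1_044
EnvHash1_045
EnvHash1_046
EnvHash1_047
EnvHash1_048
EnvHash1_049
EnvHash1_050
EnvHash1_051
EnvHash1_052
EnvHash1_053
EnvHash1_054
EnvHash1_055
EnvHash1_056
EnvHash1_057
EnvHash1_058
EnvHash1_059
EnvHash1_060
EnvHash1_061
EnvHash1_062
EnvHash1_063
EnvHash1_064
EnvHash1_065
EnvHash1_066
EnvHash1_067
EnvHash1_068
EnvHash1_069
EnvHash1_070
EnvHash1_071
EnvHash1_072
EnvHash1_073
EnvHash1_074
EnvHash1_075
EnvHash1_076
EnvHash1_077
EnvHash1_078
EnvHash1_079
EnvHash1_080
EnvHash1_081
EnvHash1_082
EnvHash1_083
EnvHash1_084
EnvHash1_085
EnvHash1_086
EnvHash1_087
EnvHash1_088
EnvHash1_089
EnvHash1_090
EnvHash1_091
EnvHash1_092
EnvHash1_093
EnvHash1_094
EnvHash1_095
EnvHash1_096
EnvHash1_097
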