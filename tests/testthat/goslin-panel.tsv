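name	level	category	class_code
PC 16:0_18:1	MOLECULAR_SPECIES	GP	GP01
PC 16:0/18:1	SN_POSITION	GP	GP01
PC 18:0_18:2	MOLECULAR_SPECIES	GP	GP01
PC 18:0/18:2	SN_POSITION	GP	GP01
PC 16:1_20:4	MOLECULAR_SPECIES	GP	GP01
PC 16:1/20:4	SN_POSITION	GP	GP01
PC 18:1_22:6	MOLECULAR_SPECIES	GP	GP01
PC 18:1/22:6	SN_POSITION	GP	GP01
PC 34:1	SPECIES	GP	GP01
PC 36:4	SPECIES	GP	GP01
PC 38:4;O	SPECIES	GP	GP01
PC 16:0/18:1(9)	STRUCTURE_DEFINED	GP	GP01
PC 16:0/18:2(9,12)	STRUCTURE_DEFINED	GP	GP01
PC 16:0/18:1(9Z)	FULL_STRUCTURE	GP	GP01
PC 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GP	GP01
PC 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GP	GP01
PC 16:0/20:4;OH	SN_POSITION	GP	GP01
PC 16:0_20:4;O	MOLECULAR_SPECIES	GP	GP01
PC 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GP	GP01
PE 16:0_18:1	MOLECULAR_SPECIES	GP	GP02
PE 16:0/18:1	SN_POSITION	GP	GP02
PE 18:0_18:2	MOLECULAR_SPECIES	GP	GP02
PE 18:0/18:2	SN_POSITION	GP	GP02
PE 16:1_20:4	MOLECULAR_SPECIES	GP	GP02
PE 16:1/20:4	SN_POSITION	GP	GP02
PE 18:1_22:6	MOLECULAR_SPECIES	GP	GP02
PE 18:1/22:6	SN_POSITION	GP	GP02
PE 34:1	SPECIES	GP	GP02
PE 36:4	SPECIES	GP	GP02
PE 38:4;O	SPECIES	GP	GP02
PE 16:0/18:1(9)	STRUCTURE_DEFINED	GP	GP02
PE 16:0/18:2(9,12)	STRUCTURE_DEFINED	GP	GP02
PE 16:0/18:1(9Z)	FULL_STRUCTURE	GP	GP02
PE 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GP	GP02
PE 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GP	GP02
PE 16:0/20:4;OH	SN_POSITION	GP	GP02
PE 16:0_20:4;O	MOLECULAR_SPECIES	GP	GP02
PE 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GP	GP02
PS 16:0_18:1	MOLECULAR_SPECIES	GP	GP03
PS 16:0/18:1	SN_POSITION	GP	GP03
PS 18:0_18:2	MOLECULAR_SPECIES	GP	GP03
PS 18:0/18:2	SN_POSITION	GP	GP03
PS 16:1_20:4	MOLECULAR_SPECIES	GP	GP03
PS 16:1/20:4	SN_POSITION	GP	GP03
PS 18:1_22:6	MOLECULAR_SPECIES	GP	GP03
PS 18:1/22:6	SN_POSITION	GP	GP03
PS 34:1	SPECIES	GP	GP03
PS 36:4	SPECIES	GP	GP03
PS 38:4;O	SPECIES	GP	GP03
PS 16:0/18:1(9)	STRUCTURE_DEFINED	GP	GP03
PS 16:0/18:2(9,12)	STRUCTURE_DEFINED	GP	GP03
PS 16:0/18:1(9Z)	FULL_STRUCTURE	GP	GP03
PS 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GP	GP03
PS 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GP	GP03
PS 16:0/20:4;OH	SN_POSITION	GP	GP03
PS 16:0_20:4;O	MOLECULAR_SPECIES	GP	GP03
PS 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GP	GP03
PG 16:0_18:1	MOLECULAR_SPECIES	GP	GP04
PG 16:0/18:1	SN_POSITION	GP	GP04
PG 18:0_18:2	MOLECULAR_SPECIES	GP	GP04
PG 18:0/18:2	SN_POSITION	GP	GP04
PG 16:1_20:4	MOLECULAR_SPECIES	GP	GP04
PG 16:1/20:4	SN_POSITION	GP	GP04
PG 18:1_22:6	MOLECULAR_SPECIES	GP	GP04
PG 18:1/22:6	SN_POSITION	GP	GP04
PG 34:1	SPECIES	GP	GP04
PG 36:4	SPECIES	GP	GP04
PG 38:4;O	SPECIES	GP	GP04
PG 16:0/18:1(9)	STRUCTURE_DEFINED	GP	GP04
PG 16:0/18:2(9,12)	STRUCTURE_DEFINED	GP	GP04
PG 16:0/18:1(9Z)	FULL_STRUCTURE	GP	GP04
PG 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GP	GP04
PG 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GP	GP04
PG 16:0/20:4;OH	SN_POSITION	GP	GP04
PG 16:0_20:4;O	MOLECULAR_SPECIES	GP	GP04
PG 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GP	GP04
PI 16:0_18:1	MOLECULAR_SPECIES	GP	GP06
PI 16:0/18:1	SN_POSITION	GP	GP06
PI 18:0_18:2	MOLECULAR_SPECIES	GP	GP06
PI 18:0/18:2	SN_POSITION	GP	GP06
PI 16:1_20:4	MOLECULAR_SPECIES	GP	GP06
PI 16:1/20:4	SN_POSITION	GP	GP06
PI 18:1_22:6	MOLECULAR_SPECIES	GP	GP06
PI 18:1/22:6	SN_POSITION	GP	GP06
PI 34:1	SPECIES	GP	GP06
PI 36:4	SPECIES	GP	GP06
PI 38:4;O	SPECIES	GP	GP06
PI 16:0/18:1(9)	STRUCTURE_DEFINED	GP	GP06
PI 16:0/18:2(9,12)	STRUCTURE_DEFINED	GP	GP06
PI 16:0/18:1(9Z)	FULL_STRUCTURE	GP	GP06
PI 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GP	GP06
PI 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GP	GP06
PI 16:0/20:4;OH	SN_POSITION	GP	GP06
PI 16:0_20:4;O	MOLECULAR_SPECIES	GP	GP06
PI 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GP	GP06
PA 16:0_18:1	MOLECULAR_SPECIES	GP	GP10
PA 16:0/18:1	SN_POSITION	GP	GP10
PA 18:0_18:2	MOLECULAR_SPECIES	GP	GP10
PA 18:0/18:2	SN_POSITION	GP	GP10
PA 16:1_20:4	MOLECULAR_SPECIES	GP	GP10
PA 16:1/20:4	SN_POSITION	GP	GP10
PA 18:1_22:6	MOLECULAR_SPECIES	GP	GP10
PA 18:1/22:6	SN_POSITION	GP	GP10
PA 34:1	SPECIES	GP	GP10
PA 36:4	SPECIES	GP	GP10
PA 38:4;O	SPECIES	GP	GP10
PA 16:0/18:1(9)	STRUCTURE_DEFINED	GP	GP10
PA 16:0/18:2(9,12)	STRUCTURE_DEFINED	GP	GP10
PA 16:0/18:1(9Z)	FULL_STRUCTURE	GP	GP10
PA 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GP	GP10
PA 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GP	GP10
PA 16:0/20:4;OH	SN_POSITION	GP	GP10
PA 16:0_20:4;O	MOLECULAR_SPECIES	GP	GP10
PA 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GP	GP10
DG 16:0_18:1	MOLECULAR_SPECIES	GL	GL02
DG 16:0/18:1	SN_POSITION	GL	GL02
DG 18:0_18:2	MOLECULAR_SPECIES	GL	GL02
DG 18:0/18:2	SN_POSITION	GL	GL02
DG 16:1_20:4	MOLECULAR_SPECIES	GL	GL02
DG 16:1/20:4	SN_POSITION	GL	GL02
DG 18:1_22:6	MOLECULAR_SPECIES	GL	GL02
DG 18:1/22:6	SN_POSITION	GL	GL02
DG 34:1	SPECIES	GL	GL02
DG 36:4	SPECIES	GL	GL02
DG 38:4;O	SPECIES	GL	GL02
DG 16:0/18:1(9)	STRUCTURE_DEFINED	GL	GL02
DG 16:0/18:2(9,12)	STRUCTURE_DEFINED	GL	GL02
DG 16:0/18:1(9Z)	FULL_STRUCTURE	GL	GL02
DG 18:1(9Z)/18:1(9Z)	FULL_STRUCTURE	GL	GL02
DG 16:0/18:1(9Z);O	STRUCTURE_DEFINED	GL	GL02
DG 16:0/20:4;OH	SN_POSITION	GL	GL02
DG 16:0_20:4;O	MOLECULAR_SPECIES	GL	GL02
DG 16:1(7)_16:1(9)	MOLECULAR_SPECIES	GL	GL02
LPC 18:1	SPECIES	GP	GP01
LPC 16:0	SPECIES	GP	GP01
LPC 18:2;O	SPECIES	GP	GP01
LPE 18:1	SPECIES	GP	GP02
LPE 16:0	SPECIES	GP	GP02
LPE 18:2;O	SPECIES	GP	GP02
MG 18:1	SPECIES	GL	GL01
MG 16:0	SPECIES	GL	GL01
MG 18:2;O	SPECIES	GL	GL01
FA 18:1	SPECIES	FA	FA01
FA 16:0	SPECIES	FA	FA01
FA 18:2;O	SPECIES	FA	FA01
CE 18:1	SPECIES	ST	ST01
CE 16:0	SPECIES	ST	ST01
CE 18:2;O	SPECIES	ST	ST01
SM 34:1;O2	SPECIES	SP	SP03
SM 42:2;O2	SPECIES	SP	SP03
SM 18:1;O2/24:0	SN_POSITION	SP	SP03
SM 18:1;O2_24:1	MOLECULAR_SPECIES	SP	SP03
Cer 34:1;O2	SPECIES	SP	SP02
Cer 42:2;O2	SPECIES	SP	SP02
Cer 18:1;O2/24:0	SN_POSITION	SP	SP02
Cer 18:1;O2_24:1	MOLECULAR_SPECIES	SP	SP02
HexCer 34:1;O2	SPECIES	SP	SP05
HexCer 42:2;O2	SPECIES	SP	SP05
HexCer 18:1;O2/24:0	SN_POSITION	SP	SP05
HexCer 18:1;O2_24:1	MOLECULAR_SPECIES	SP	SP05
PC O-34:1	SPECIES	GP	GP01
PC P-36:2	SPECIES	GP	GP01
PC O-16:0_18:1	MOLECULAR_SPECIES	GP	GP01
PC O-16:0/18:1	SN_POSITION	GP	GP01
PC P-18:0_20:4	MOLECULAR_SPECIES	GP	GP01
PE O-34:1	SPECIES	GP	GP02
PE P-36:2	SPECIES	GP	GP02
PE O-16:0_18:1	MOLECULAR_SPECIES	GP	GP02
PE O-16:0/18:1	SN_POSITION	GP	GP02
PE P-18:0_20:4	MOLECULAR_SPECIES	GP	GP02
PC 34:1 [M+H]+	SPECIES	GP	GP01
PE 16:0_18:1 [M-H]-	MOLECULAR_SPECIES	GP	GP02
TG 52:2 [M+NH4]+	SPECIES	GL	GL03
TG 16:0_18:1_18:1	MOLECULAR_SPECIES	GL	GL03
TG 16:0/18:1/18:2	SN_POSITION	GL	GL03
TG 52:2	SPECIES	GL	GL03
TG 16:0/18:1(9)/18:2(9,12)	STRUCTURE_DEFINED	GL	GL03
PC 32:0	SPECIES	GP	GP01
PC 40:6;O2	SPECIES	GP	GP01
PC 14:0_22:6	MOLECULAR_SPECIES	GP	GP01
PE 32:0	SPECIES	GP	GP02
PE 40:6;O2	SPECIES	GP	GP02
PE 14:0_22:6	MOLECULAR_SPECIES	GP	GP02
PS 32:0	SPECIES	GP	GP03
PS 40:6;O2	SPECIES	GP	GP03
PS 14:0_22:6	MOLECULAR_SPECIES	GP	GP03
PG 32:0	SPECIES	GP	GP04
PG 40:6;O2	SPECIES	GP	GP04
PG 14:0_22:6	MOLECULAR_SPECIES	GP	GP04
PI 32:0	SPECIES	GP	GP06
PI 40:6;O2	SPECIES	GP	GP06
PI 14:0_22:6	MOLECULAR_SPECIES	GP	GP06
PA 32:0	SPECIES	GP	GP10
PA 40:6;O2	SPECIES	GP	GP10
PA 14:0_22:6	MOLECULAR_SPECIES	GP	GP10
DG 32:0	SPECIES	GL	GL02
DG 40:6;O2	SPECIES	GL	GL02
DG 14:0_22:6	MOLECULAR_SPECIES	GL	GL02
LPC 20:4;OH	SPECIES	GP	GP01
LPE 20:4;OH	SPECIES	GP	GP02
FA 20:4;OH	SPECIES	FA	FA01
Cer 18:1;O2/24:0;OH	SN_POSITION	SP	SP02
SM 18:1;O2/16:0	SN_POSITION	SP	SP03
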