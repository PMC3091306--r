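# Identify phosphatidylcholine (PC) species in positive-ion shotgun spectra:
# precursors matching the PC sum-composition constraint whose MS/MS spectra
# contain the phosphorylcholine head-group fragment at m/z 184.07.
QUERYNAME = Phosphatidylcholine;

DEFINE headPC = 'C5 H15 O4 N1 P1' WITH CHG = +1;
DEFINE prPC = 'C[30..48] H[30..200] N[1] O[8] P[1]' WITH CHG = +1, DBR = (1.5, 7.5);

IDENTIFY
  prPC IN MS1+ AND
  headPC IN MS2+;

SUCHTHAT
  isEven(prPC.chemsc[C]);

REPORT
  MASS = prPC.mass;
  NAME = "PC [%d:%d]" % "((prPC.chemsc - headPC.chemsc)[C] - 3, prPC.chemsc[db] - 1.5)";
  CHEMSC = prPC.chemsc;
  ERROR = "%dppm" % "(prPC.errppm)";
  INTENS = prPC.intensity;
  FRAGINTENS = headPC.intensity;;
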