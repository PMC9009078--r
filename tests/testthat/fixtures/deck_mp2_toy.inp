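! DLPNO-MP2 RIJCOSX DefGrid3 NMR
%pointcharges "toy.pc"
%mp2
  UseMultilevel true
  PNOFragment 1 NormalPNO
  PNORest LoosePNO
end
%eprnmr
  Nuclei = 1:3 { shift }
end
* xyz 0 1
O(1)     0.69456909     1.36054212     1.74826512 newGTO "pcSseg-3" end
H(1)     1.24589968     0.79844613     1.20391732 newGTO "pcSseg-3" end
H(1)     1.14077098     1.38661353     2.59470235 newGTO "pcSseg-3" end
O(2)     3.26354184    -1.38945788     4.16058140 newGTO "def2-TZVP" end
H(2)     2.71221126    -1.95155387     4.70492920 newGTO "def2-TZVP" end
H(2)     2.81733995    -1.36338647     3.31414417 newGTO "def2-TZVP" end
O(2)     3.26354184     4.11054212     4.16058140 newGTO "def2-TZVP" end
H(2)     2.71221126     3.54844613     4.70492920 newGTO "def2-TZVP" end
H(2)     2.81733995     4.13661353     3.31414417 newGTO "def2-TZVP" end
*
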