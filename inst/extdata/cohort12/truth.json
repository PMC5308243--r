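[
  {
    "gene_id": "CSAB_NaTx1",
    "protein": "VLGLAGTKVFVLNDACLVFIDITVCDECAWSIYSVFLVATTIQGFPIEHKRSSCVRFRDFFGGFASSLEKAEQPTMPYDTLIKSA",
    "signature": true,
    "introns": [
      {
        "gene_id": "CSAB_NaTx1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 19,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      }
    ]
  },
  {
    "gene_id": "CSAB_KTx1",
    "protein": "SRAIKYPWMYNAERIAPDSLRPWRSTSGLAQYMRVTHQPGQDIPSQNGHVYCHARRELQP",
    "signature": true,
    "introns": [
      {
        "gene_id": "CSAB_KTx1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 22,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      }
    ]
  },
  {
    "gene_id": "CSAB_KTxB",
    "protein": "MPWEPGCDTTLSFVSCPRERLAVETWSLQGSRNGTGTPLLPLDNNSCAHQYDQPFFRRISRQGPLRAGGCNSGIIQRCTHSPICSGAVTK",
    "signature": true,
    "introns": [
      {
        "gene_id": "CSAB_KTxB",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 21,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      },
      {
        "gene_id": "CSAB_KTxB",
        "ordinal": 2,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 60,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 39
      }
    ]
  },
  {
    "gene_id": "CSAB_KTx_UTR",
    "protein": "SPTSSVLLKSAEGAQCVLAFFLAVMYQLEAISVEEFCRRCYRSGSPQSNLYRLSLC",
    "signature": true,
    "introns": [
      {
        "gene_id": "CSAB_KTx_UTR",
        "ordinal": 1,
        "region": "UTR5",
        "phase": null,
        "interrupted_codon_index": null,
        "precursor_region": "UTR5",
        "offset_from_cleavage": null
      },
      {
        "gene_id": "CSAB_KTx_UTR",
        "ordinal": 2,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 28,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      }
    ]
  },
  {
    "gene_id": "CSAB_DFN_UTR",
    "protein": "DVPSLQYFGYQRCLTISRDPYSRTLLKEIIQYHEGAAFHSSINILAPWDDVAVSCRQDRLWQRDGNAARVPFHLSIKERS",
    "signature": true,
    "introns": [
      {
        "gene_id": "CSAB_DFN_UTR",
        "ordinal": 1,
        "region": "UTR5",
        "phase": null,
        "interrupted_codon_index": null,
        "precursor_region": "UTR5",
        "offset_from_cleavage": null
      },
      {
        "gene_id": "CSAB_DFN_UTR",
        "ordinal": 2,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 23,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      }
    ]
  },
  {
    "gene_id": "ICK_KTx1",
    "protein": "HYALTLSSKMRERSGRKIAAPPAPSLRLLIRALTHTVALSQGFTSNPKGKEAYLKCSINPISTVHSIPSSTRRLVYLPPNILPDLVQTRNRRRCST",
    "signature": true,
    "introns": [
      {
        "gene_id": "ICK_KTx1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 26,
        "precursor_region": "PROPEPTIDE",
        "offset_from_cleavage": 2
      },
      {
        "gene_id": "ICK_KTx1",
        "ordinal": 2,
        "region": "CODING",
        "phase": 2,
        "interrupted_codon_index": 34,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 10
      }
    ]
  },
  {
    "gene_id": "ICK_CAL1",
    "protein": "DAPSIATRLAPLRLSGRQVLTIDVHCLTILELRMGLGALRSNKIPLPKSIISTRSLAAEILHVPNLFAVRSFYPEMRTDNSKLRIVLRKLGG",
    "signature": true,
    "introns": [
      {
        "gene_id": "ICK_CAL1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 24,
        "precursor_region": "PROPEPTIDE",
        "offset_from_cleavage": 2
      },
      {
        "gene_id": "ICK_CAL1",
        "ordinal": 2,
        "region": "CODING",
        "phase": 2,
        "interrupted_codon_index": 31,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 9
      }
    ]
  },
  {
    "gene_id": "ICK_CAL2",
    "protein": "QELAWGPSGSLNILSAQSCKTWYQFGIFVYGHGCLTGTPGIIRPSTIRMPVGTRATHRHMGQLSISHVVLLRVSQPTEVTVCRSQNSTNGKSFEA",
    "signature": true,
    "introns": [
      {
        "gene_id": "ICK_CAL2",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 25,
        "precursor_region": "PROPEPTIDE",
        "offset_from_cleavage": 2
      },
      {
        "gene_id": "ICK_CAL2",
        "ordinal": 2,
        "region": "CODING",
        "phase": 2,
        "interrupted_codon_index": 33,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 10
      }
    ]
  },
  {
    "gene_id": "AMP_Kn1",
    "protein": "MEQRRSHGRLYRRLQNIASSLLNGPGTWYRVIRGDNGVSSRVRGSASCFYVRTIGCPL",
    "signature": true,
    "introns": [
      {
        "gene_id": "AMP_Kn1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 23,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      }
    ]
  },
  {
    "gene_id": "PROT_ChTP1",
    "protein": "DHSFCTSKDDTVVLIQVVSNLQSVFSRIGQDPVRALSLSVKRYTVGGTDETLCQSASFSLHSTTPPGGSAAAVIQGSRGDVQYNNSAVLPVRRQFSARQWCGLVFKHVVIQVAKVSTVMGQSTRGRIRGSHYTFLVILAFGATGGLIGVL",
    "signature": true,
    "introns": [
      {
        "gene_id": "PROT_ChTP1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 18,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 0
      },
      {
        "gene_id": "PROT_ChTP1",
        "ordinal": 2,
        "region": "CODING",
        "phase": 0,
        "interrupted_codon_index": 50,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 32
      },
      {
        "gene_id": "PROT_ChTP1",
        "ordinal": 3,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 80,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 62
      },
      {
        "gene_id": "PROT_ChTP1",
        "ordinal": 4,
        "region": "CODING",
        "phase": 2,
        "interrupted_codon_index": 110,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 92
      }
    ]
  },
  {
    "gene_id": "PROT_ChTP2",
    "protein": "IAKTLDFTSEWPPHRHLQFTNGPIDVSGRGLFISAEYYFLRPPARVKSTVAAGPVKINIIGTKWPIVLIYQVFALIGLKCRGCNFRLYEITQYKGEHLSFSWSVGFSHSPLVCRHSSVDHRSADLYCSHLLELLPCDLIAFLCLRPHPAG",
    "signature": true,
    "introns": [
      {
        "gene_id": "PROT_ChTP2",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 19,
        "precursor_region": "SIGNAL",
        "offset_from_cleavage": -1
      },
      {
        "gene_id": "PROT_ChTP2",
        "ordinal": 2,
        "region": "CODING",
        "phase": 0,
        "interrupted_codon_index": 60,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 40
      },
      {
        "gene_id": "PROT_ChTP2",
        "ordinal": 3,
        "region": "CODING",
        "phase": 2,
        "interrupted_codon_index": 95,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 75
      }
    ]
  },
  {
    "gene_id": "KUNITZ_PI1",
    "protein": "TLSNPRWPSLPRPRGEFEFKIQPARTGLADTRIRAETRCASHRGIRFLAVDLGTSMAMGRILRSRPYLNLPAEQPSFWDPR",
    "signature": true,
    "introns": [
      {
        "gene_id": "KUNITZ_PI1",
        "ordinal": 1,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 20,
        "precursor_region": "SIGNAL",
        "offset_from_cleavage": -1
      },
      {
        "gene_id": "KUNITZ_PI1",
        "ordinal": 2,
        "region": "CODING",
        "phase": 1,
        "interrupted_codon_index": 50,
        "precursor_region": "MATURE",
        "offset_from_cleavage": 29
      }
    ]
  }
]
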