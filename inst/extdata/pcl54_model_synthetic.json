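{
 "format_version": 1,
 "genes": [
  {
   "gene_id": "NCAM1",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "ITGA6",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SDC1",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "PTEN",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "TUSC2",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "TAGLN2",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "MKI67",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "MCM2",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "CENPM",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SRSF10",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SF3A2",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "PUF60",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "ROCK1",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "DOCK11",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "DLC1",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "CHEK1",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "DCLRE1C",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SLFN11",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "XPO1",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "PHF19",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "DCK",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-22",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-23",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-24",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-25",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-26",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-27",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-28",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-29",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-30",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-31",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-32",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-33",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-34",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-35",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-36",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-37",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-38",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-39",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-40",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-41",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-42",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-43",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-44",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-45",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-46",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-47",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-48",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-49",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-50",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-51",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-52",
   "sign": -1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-53",
   "sign": 1,
   "weight": 1.0
  },
  {
   "gene_id": "SYNTHETIC-54",
   "sign": -1,
   "weight": 1.0
  }
 ],
 "threshold": 3.55,
 "provenance": "packaged_table2",
 "metadata": "SYNTHETIC STAND-IN GENE LIST. The published 54-gene PCL-like classifier is represented here only by its packaged constants (54 gene entries, decision threshold 3.55, inclusive rule score >= threshold). Gene identities are NOT the published ones: 21 symbols are genes the source publication names as CTC-associated or PCL-like-upregulated in its prose; the remaining 33 are placeholders named SYNTHETIC-*. Signs and unit weights are likewise placeholders. Standardization statistics must be supplied from a user-declared reference cohort at scoring time."
}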