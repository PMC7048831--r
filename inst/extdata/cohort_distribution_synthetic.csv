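"case_id","MGMT","IDH","CODEL","ATRX","TERT","survival_months","event"
"LGG-001","methylated","mutant","codeleted","WT","mutant",18.2,0
"LGG-002","methylated","mutant","codeleted","WT","mutant",71.9,1
"LGG-003","methylated","mutant","codeleted","WT","mutant",15,0
"LGG-004","methylated","mutant","codeleted","WT","mutant",42.7,1
"LGG-005","methylated","mutant","codeleted","WT","mutant",80.1,1
"LGG-006","methylated","mutant","codeleted","WT","mutant",71.6,0
"LGG-007","methylated","mutant","codeleted","WT","mutant",324.7,1
"LGG-008","methylated","mutant","codeleted","WT","mutant",15.2,0
"LGG-009","methylated","mutant","codeleted","WT","mutant",31.1,0
"LGG-010","methylated","mutant","codeleted","WT","mutant",28.8,1
"LGG-011","methylated","mutant","codeleted","WT","mutant",37.9,0
"LGG-012","methylated","mutant","codeleted","WT","mutant",78.1,1
"LGG-013","methylated","mutant","codeleted","WT","mutant",75.2,1
"LGG-014","methylated","mutant","codeleted","WT","mutant",6.4,0
"LGG-015","methylated","mutant","codeleted","WT","mutant",22.8,1
"LGG-016","methylated","mutant","codeleted","WT","mutant",43.7,0
"LGG-017","methylated","mutant","codeleted","WT","mutant",109.8,0
"LGG-018","methylated","mutant","codeleted","WT","mutant",129.9,0
"LGG-019","methylated","mutant","codeleted","WT","mutant",37,0
"LGG-020","methylated","mutant","codeleted","WT","mutant",8.3,0
"LGG-021","methylated","mutant","codeleted","WT","mutant",63.2,0
"LGG-022","methylated","mutant","codeleted","WT","mutant",29.3,1
"LGG-023","methylated","mutant","codeleted","WT","mutant",61.3,0
"LGG-024","methylated","mutant","codeleted","WT","mutant",124.3,0
"LGG-025","methylated","mutant","codeleted","WT","mutant",2,0
"LGG-026","methylated","mutant","codeleted","WT","mutant",65.9,0
"LGG-027","methylated","mutant","codeleted","WT","mutant",253.5,1
"LGG-028","methylated","mutant","non-codeleted","mutant","WT",10.5,1
"LGG-029","methylated","mutant","non-codeleted","mutant","WT",10.6,1
"LGG-030","methylated","mutant","non-codeleted","mutant","WT",15.7,1
"LGG-031","methylated","mutant","non-codeleted","mutant","WT",9.9,0
"LGG-032","methylated","mutant","non-codeleted","mutant","WT",66.8,0
"LGG-033","methylated","mutant","non-codeleted","mutant","WT",96.2,0
"LGG-034","methylated","mutant","non-codeleted","mutant","WT",10.7,1
"LGG-035","methylated","mutant","non-codeleted","mutant","WT",48.5,1
"LGG-036","methylated","mutant","non-codeleted","mutant","WT",21.9,1
"LGG-037","methylated","mutant","non-codeleted","mutant","WT",312.5,1
"LGG-038","methylated","mutant","non-codeleted","mutant","WT",48.7,0
"LGG-039","methylated","mutant","non-codeleted","mutant","WT",48.1,1
"LGG-040","methylated","mutant","non-codeleted","mutant","WT",63.5,1
"LGG-041","methylated","mutant","non-codeleted","mutant","WT",8.4,0
"LGG-042","methylated","mutant","non-codeleted","mutant","WT",14.6,1
"LGG-043","methylated","mutant","non-codeleted","mutant","WT",16.8,1
"LGG-044","methylated","mutant","non-codeleted","mutant","WT",5.3,0
"LGG-045","methylated","mutant","non-codeleted","mutant","WT",50.1,1
"LGG-046","methylated","mutant","non-codeleted","mutant","WT",48.4,1
"LGG-047","methylated","mutant","non-codeleted","mutant","WT",180.1,0
"LGG-048","methylated","mutant","non-codeleted","mutant","WT",37,1
"LGG-049","methylated","mutant","non-codeleted","mutant","WT",147.4,1
"LGG-050","methylated","mutant","non-codeleted","mutant","WT",52.6,1
"LGG-051","methylated","mutant","non-codeleted","mutant","WT",71.8,0
"LGG-052","methylated","mutant","non-codeleted","mutant","WT",69.1,1
"LGG-053","methylated","mutant","non-codeleted","mutant","WT",99,0
"LGG-054","methylated","mutant","non-codeleted","mutant","WT",82.8,1
"LGG-055","methylated","mutant","non-codeleted","mutant","WT",101.1,0
"LGG-056","methylated","mutant","non-codeleted","mutant","WT",63.3,0
"LGG-057","methylated","mutant","non-codeleted","mutant","WT",34.7,0
"LGG-058","methylated","mutant","non-codeleted","mutant","WT",3,1
"LGG-059","methylated","mutant","non-codeleted","mutant","mutant",103.9,1
"LGG-060","methylated","mutant","non-codeleted","mutant","mutant",29,0
"LGG-061","methylated","mutant","non-codeleted","mutant","mutant",92.3,0
"LGG-062","methylated","mutant","non-codeleted","mutant","mutant",22.6,0
"LGG-063","methylated","mutant","non-codeleted","WT","WT",50.3,1
"LGG-064","methylated","mutant","non-codeleted","WT","WT",26.9,0
"LGG-065","methylated","mutant","non-codeleted","WT","WT",8.2,1
"LGG-066","methylated","mutant","non-codeleted","WT","WT",22.1,0
"LGG-067","methylated","mutant","non-codeleted","WT","WT",33.5,0
"LGG-068","methylated","mutant","non-codeleted","WT","WT",7.2,0
"LGG-069","methylated","mutant","non-codeleted","WT","WT",39.6,0
"LGG-070","methylated","mutant","non-codeleted","WT","WT",7.3,0
"LGG-071","methylated","mutant","non-codeleted","WT","WT",208.9,1
"LGG-072","methylated","mutant","non-codeleted","WT","WT",142.4,1
"LGG-073","methylated","mutant","non-codeleted","WT","WT",73.8,1
"LGG-074","methylated","mutant","non-codeleted","WT","WT",47.9,1
"LGG-075","methylated","mutant","non-codeleted","WT","WT",59.9,1
"LGG-076","methylated","mutant","non-codeleted","WT","WT",11.5,1
"LGG-077","methylated","mutant","non-codeleted","WT","WT",188.7,1
"LGG-078","methylated","mutant","non-codeleted","WT","WT",22.2,0
"LGG-079","methylated","mutant","non-codeleted","WT","WT",38.3,0
"LGG-080","methylated","mutant","non-codeleted","WT","WT",13.9,1
"LGG-081","methylated","mutant","non-codeleted","WT","WT",17.8,0
"LGG-082","methylated","mutant","non-codeleted","WT","WT",3.9,0
"LGG-083","methylated","mutant","non-codeleted","WT","WT",37.4,0
"LGG-084","methylated","mutant","non-codeleted","WT","WT",66.2,1
"LGG-085","methylated","mutant","non-codeleted","WT","WT",77.2,0
"LGG-086","unmethylated","WT","non-codeleted","mutant","WT",97.3,0
"LGG-087","unmethylated","WT","non-codeleted","mutant","WT",9.3,0
"LGG-088","unmethylated","WT","non-codeleted","mutant","WT",215,0
"LGG-089","unmethylated","WT","non-codeleted","mutant","WT",3.6,0
"LGG-090","unmethylated","WT","non-codeleted","mutant","WT",16.3,0
"LGG-091","unmethylated","WT","non-codeleted","mutant","WT",67.6,0
"LGG-092","unmethylated","WT","non-codeleted","mutant","WT",22,0
"LGG-093","unmethylated","WT","non-codeleted","mutant","WT",103.7,1
"LGG-094","unmethylated","WT","non-codeleted","WT","mutant",118.9,1
"LGG-095","unmethylated","WT","non-codeleted","WT","mutant",79.7,0
"LGG-096","unmethylated","WT","non-codeleted","WT","mutant",9.8,0
"LGG-097","unmethylated","WT","non-codeleted","WT","mutant",4,1
"LGG-098","unmethylated","WT","non-codeleted","WT","mutant",24.7,1
"LGG-099","unmethylated","WT","non-codeleted","WT","mutant",27.9,0
"LGG-100","methylated","WT","non-codeleted","WT","mutant",78.5,1
"LGG-101","methylated","WT","non-codeleted","WT","mutant",57.8,0
"LGG-102","methylated","WT","non-codeleted","WT","mutant",9.7,1
"LGG-103","methylated","WT","non-codeleted","WT","mutant",45.9,0
"LGG-104","methylated","WT","non-codeleted","WT","mutant",3.1,0
"LGG-105","methylated","WT","non-codeleted","WT","mutant",4.8,1
"LGG-106","","WT","non-codeleted","WT","mutant",148.4,1
"LGG-107","","WT","non-codeleted","WT","mutant",23.9,0
"LGG-108","","WT","non-codeleted","WT","mutant",26.3,0
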