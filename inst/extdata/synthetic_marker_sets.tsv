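#rank	taxon	parent_taxon	marker_sets
domain	d__SynBacteria	root	[[BAC0001,BAC0002,BAC0003,BAC0004],[BAC0005,BAC0006,BAC0007,BAC0008,BAC0009,BAC0010],[BAC0011,BAC0012,BAC0013],[BAC0014,BAC0015,BAC0016,BAC0017,BAC0018],[BAC0019,BAC0020],[BAC0021,BAC0022,BAC0023,BAC0024,BAC0025,BAC0026,BAC0027],[BAC0028,BAC0029,BAC0030,BAC0031],[BAC0032,BAC0033,BAC0034,BAC0035,BAC0036,BAC0037],[BAC0038,BAC0039,BAC0040],[BAC0041,BAC0042,BAC0043,BAC0044,BAC0045],[BAC0046,BAC0047],[BAC0048,BAC0049,BAC0050,BAC0051,BAC0052,BAC0053,BAC0054],[BAC0055,BAC0056,BAC0057,BAC0058],[BAC0059,BAC0060,BAC0061,BAC0062,BAC0063,BAC0064],[BAC0065,BAC0066,BAC0067],[BAC0068,BAC0069,BAC0070,BAC0071,BAC0072],[BAC0073,BAC0074],[BAC0075,BAC0076,BAC0077,BAC0078,BAC0079,BAC0080,BAC0081],[BAC0082,BAC0083,BAC0084,BAC0085],[BAC0086,BAC0087,BAC0088,BAC0089,BAC0090,BAC0091],[BAC0092,BAC0093,BAC0094],[BAC0095,BAC0096,BAC0097,BAC0098,BAC0099],[BAC0100,BAC0101],[BAC0102,BAC0103,BAC0104]]
domain	d__SynArchaea	root	[[ARC0001,ARC0002,ARC0003,ARC0004],[ARC0005,ARC0006,ARC0007,ARC0008,ARC0009,ARC0010],[ARC0011,ARC0012,ARC0013],[ARC0014,ARC0015,ARC0016,ARC0017,ARC0018],[ARC0019,ARC0020],[ARC0021,ARC0022,ARC0023,ARC0024,ARC0025,ARC0026,ARC0027],[ARC0028,ARC0029,ARC0030,ARC0031],[ARC0032,ARC0033,ARC0034,ARC0035,ARC0036,ARC0037],[ARC0038,ARC0039,ARC0040],[ARC0041,ARC0042,ARC0043,ARC0044,ARC0045],[ARC0046,ARC0047],[ARC0048,ARC0049,ARC0050,ARC0051,ARC0052,ARC0053,ARC0054],[ARC0055,ARC0056,ARC0057,ARC0058],[ARC0059,ARC0060,ARC0061,ARC0062,ARC0063,ARC0064],[ARC0065,ARC0066,ARC0067],[ARC0068,ARC0069,ARC0070,ARC0071,ARC0072],[ARC0073,ARC0074],[ARC0075,ARC0076,ARC0077,ARC0078,ARC0079,ARC0080,ARC0081],[ARC0082,ARC0083,ARC0084,ARC0085],[ARC0086,ARC0087,ARC0088]]
phylum	p__SynFirmia	d__SynBacteria	[[PFI0001,PFI0002,PFI0003,PFI0004],[PFI0005,PFI0006,PFI0007,PFI0008,PFI0009,PFI0010],[PFI0011,PFI0012,PFI0013],[PFI0014,PFI0015,PFI0016,PFI0017,PFI0018],[PFI0019,PFI0020],[PFI0021,PFI0022,PFI0023,PFI0024]]
phylum	p__SynProteia	d__SynBacteria	[[PPR0001,PPR0002,PPR0003,PPR0004],[PPR0005,PPR0006,PPR0007,PPR0008,PPR0009,PPR0010],[PPR0011,PPR0012,PPR0013],[PPR0014,PPR0015,PPR0016,PPR0017,PPR0018],[PPR0019,PPR0020],[PPR0021,PPR0022,PPR0023,PPR0024]]
phylum	p__SynEuryia	d__SynArchaea	[[PEU0001,PEU0002,PEU0003,PEU0004],[PEU0005,PEU0006,PEU0007,PEU0008,PEU0009,PEU0010],[PEU0011,PEU0012,PEU0013],[PEU0014,PEU0015,PEU0016,PEU0017,PEU0018],[PEU0019,PEU0020],[PEU0021,PEU0022,PEU0023,PEU0024]]
phylum	p__SynCrenia	d__SynArchaea	[[PCR0001,PCR0002,PCR0003,PCR0004],[PCR0005,PCR0006,PCR0007,PCR0008,PCR0009,PCR0010],[PCR0011,PCR0012,PCR0013],[PCR0014,PCR0015,PCR0016,PCR0017,PCR0018],[PCR0019,PCR0020],[PCR0021,PCR0022,PCR0023,PCR0024]]
class	c__SynBacilli	p__SynFirmia	[[CBA0001,CBA0002,CBA0003,CBA0004],[CBA0005,CBA0006,CBA0007,CBA0008,CBA0009,CBA0010],[CBA0011,CBA0012,CBA0013],[CBA0014,CBA0015,CBA0016,CBA0017,CBA0018],[CBA0019,CBA0020]]
class	c__SynClostria	p__SynFirmia	[[CCL0001,CCL0002,CCL0003,CCL0004],[CCL0005,CCL0006,CCL0007,CCL0008,CCL0009,CCL0010],[CCL0011,CCL0012,CCL0013],[CCL0014,CCL0015,CCL0016,CCL0017,CCL0018],[CCL0019,CCL0020]]
class	c__SynGammia	p__SynProteia	[[CGA0001,CGA0002,CGA0003,CGA0004],[CGA0005,CGA0006,CGA0007,CGA0008,CGA0009,CGA0010],[CGA0011,CGA0012,CGA0013],[CGA0014,CGA0015,CGA0016,CGA0017,CGA0018],[CGA0019,CGA0020]]
class	c__SynDeltia	p__SynProteia	[[CDE0001,CDE0002,CDE0003,CDE0004],[CDE0005,CDE0006,CDE0007,CDE0008,CDE0009,CDE0010],[CDE0011,CDE0012,CDE0013],[CDE0014,CDE0015,CDE0016,CDE0017,CDE0018],[CDE0019,CDE0020]]
class	c__SynMethania	p__SynEuryia	[[CME0001,CME0002,CME0003,CME0004],[CME0005,CME0006,CME0007,CME0008,CME0009,CME0010],[CME0011,CME0012,CME0013],[CME0014,CME0015,CME0016,CME0017,CME0018],[CME0019,CME0020]]
class	c__SynThermia	p__SynCrenia	[[CTH0001,CTH0002,CTH0003,CTH0004],[CTH0005,CTH0006,CTH0007,CTH0008,CTH0009,CTH0010],[CTH0011,CTH0012,CTH0013],[CTH0014,CTH0015,CTH0016,CTH0017,CTH0018],[CTH0019,CTH0020]]
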