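module_id	name	definition
MSYN001	glycolysis core stand-in (synthetic)	K00001 K00002 K00003
MSYN002	PRPP biosynthesis stand-in (synthetic)	K00011 (K00012,K00013)
MSYN003	acetoclastic methanogenesis stand-in (synthetic)	K00101 K00102+K00103 K00104
MSYN004	reductive citrate cycle stand-in (synthetic)	(K00201,K00202) K00203 K00204-K00205
MSYN005	C1-unit interconversion stand-in (synthetic)	K00301 K00302 (K00303,K00304) K00305
MSYN006	Wood-Ljungdahl pathway stand-in (synthetic)	K00401+K00402 K00403 (K00404,K00405)
MSYN007	hydrogenotrophic methanogenesis stand-in (synthetic)	K00501 K00502 K00503+K00504-K00505
MSYN008	single-step module stand-in (synthetic)	K00601,K00602
MSYN009	module with optional step (synthetic)	K00701 -K00702 K00703
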