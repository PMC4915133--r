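ppi_verbs:
- activate
- associate
- bind
- crosslink
- interact
ptm_verbs:
- acetylate
- methylate
noun_triggers:
- complex
- dimer
- heterodimer
indirect_triggers:
- block
- mediate
process_triggers:
- activation
- activity
- association
- interaction
technique_keywords:
- 2-hybrid
- bifc
- cosedimentation
- itc
- pulldown
part_nouns:
- cleft
- domain
- fragment
- loop
- motif
- region
- residue
- site
- subunit
- tail
- terminus
collection_nouns:
- factor
- ligand
- member
- molecule
- partner
- protein
- receptor
goal_phrases:
- to investigate
- to determine
- to test
- to examine
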