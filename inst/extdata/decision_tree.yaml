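# Decision-tree adjacency for menstrual cycle status classification.
# Each question node has a yes/no child; children are either question nodes
# or leaf codes. The root is q_menarche (entered from the root concept
# "female"). The natural-cycle subtree is entered at q_oligo and is also
# walked per closed cycle. The exact internal ordering of the published
# natural-cycle questions is reconstructed from the leaf criteria; the
# adjacency is data so alternative orderings are testable.
root: q_menarche
natural_subtree_root: q_oligo
leaves: [A1, A2, FHA, B1, B1_PROBABLE_OV, C1, D1, D2, E, F, HC]
nodes:
  q_menarche:
    question: "Has menarche (the first menstrual bleed) occurred?"
    yes: q_contraception
    no: q_age15
  q_age15:
    question: "Is the individual 15 years of age or older?"
    yes: A2
    no: q_age14_nosec
  q_age14_nosec:
    question: "Is the individual 14 or older with no secondary sex characteristics present?"
    yes: A2
    no: A1
  q_contraception:
    question: "Is hormonal contraception (other than a copper IUD) currently used?"
    yes: HC
    no: q_recent_bleed
  q_recent_bleed:
    question: "Has a menstrual bleed occurred within the last 3 months?"
    yes: q_oligo
    no: FHA
  q_oligo:
    question: "Is the cycle prolonged (> 35 days) or are there 9 or fewer menstrual bleeds in the year?"
    yes: F
    no: q_short_cycle
  q_short_cycle:
    question: "Is the cycle shorter than 21 days?"
    yes: D2
    no: q_lh_tested
  q_lh_tested:
    question: "Were urinary LH ovulation tests completed this cycle (and readable at this monitoring tier)?"
    yes: q_lh_positive
    no: B1
  q_lh_positive:
    question: "Was any urinary LH test positive (LH surge detected)?"
    yes: q_short_luteal
    no: E
  q_short_luteal:
    question: "Is the luteal phase shorter than 14 days?"
    yes: D2
    no: q_p4_available
  q_p4_available:
    question: "Was mid-luteal serum progesterone measured (and readable at this monitoring tier)?"
    yes: q_p4_above
    no: B1_PROBABLE_OV
  q_p4_above:
    question: "Is mid-luteal progesterone above 16 nmol/L?"
    yes: C1
    no: D1
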