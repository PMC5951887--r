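# 32-item HIV Stigma Scale (revised version): four subscales of unique
# items, identified by their instrument numbering. Items 8 and 21 are
# reverse-scored.
subscales:
  personalized_stigma:
    - item_18
    - item_24
    - item_26
    - item_28
    - item_29
    - item_32
    - item_33
    - item_35
    - item_36
    - item_38
    - item_39
  disclosure_concerns:
    - item_1
    - item_4
    - item_6
    - item_17
    - item_21
    - item_22
    - item_25
    - item_37
  public_attitudes:
    - item_5
    - item_9
    - item_10
    - item_14
    - item_16
    - item_20
  negative_self_image:
    - item_2
    - item_3
    - item_7
    - item_8
    - item_12
    - item_15
    - item_23
reverse_items:
  - item_8
  - item_21
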