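# Default condition-based labeling rules, in priority order
# (first matching rule wins; samples matching none stay unlabeled).
- when: {known_mixotroph: yes, light: yes, bacteria_present: yes}
  label: mixotrophy
- when: {known_mixotroph: yes, light: yes, bacteria_present: no}
  label: phototrophy
- when: {literature_label: heterotrophy}
  label: heterotrophy
- when: {literature_label: mixotrophy}
  label: mixotrophy
- when: {literature_label: phototrophy}
  label: phototrophy
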