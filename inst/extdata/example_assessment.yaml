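# Example value-element assessment for a hypothetical ultra-orphan drug.
# One level token per element; see marie_criteria() for the vocabulary.
drug_id: example-ultra-orphan
efficacy: superiority                 # superiority over active comparator (20)
safety: continued_surveillance        # post-marketing surveillance note (10)
scientific_novelty: novel_mechanism   # novel mechanism of action (10)
clinical_positioning: first_option    # new or first treatment option (10)
unmet_needs: low_satisfaction_low_contribution   # 5
qol: improved                         # 5
true_endpoints: not_observed          # 0
productivity_loss: no_reports         # 0
convenience: improved                 # self-administration possible (5)
diagnosis: not_observed               # 0
pediatric_use: approved               # 10
others: not_applicable                # 0
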