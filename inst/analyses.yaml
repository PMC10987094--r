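# Registry of the statistical battery. Each group maps to one exported
# operation; `models` lists the effect tables the operation must return.
analyses:
  behaviour:
    operation: behaviour_analysis
    models: [rt_full, rt_correct, rt_error, accuracy]
  ssvep:
    operation: ssvep_analyses
    models: [evidence_cue, baseline_cued, target_nontarget,
             evidence_cue_exposure, pre_post_response]
  ssvep_behaviour:
    operation: ssvep_behaviour_link
    models: [accuracy_link, rt_link]
  mb_alpha:
    operation: mb_alpha_analyses
    models: [mb_lateralization, alpha]
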