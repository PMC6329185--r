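# Base bleeding-management rule table for recommend().
#
# The established ROTEM-guided algorithm that the Ricotem+ path extends is
# institution-specific; configure it here rather than relying on built-in
# clinical thresholds (the package ships none). Each rule:
#   rule_id:    unique name, echoed in the rule trace
#   parameter:  a bleeding_case ROTEM field
#               (extem_ct_s | fibtem_mcf_mm | extem_mcf_mm)
#   op:         lt | le | gt | ge
#   threshold:  numeric, in the parameter's units
#   action:     free-text action code appended when the rule fires
#   rationale:  justification echoed in the rule trace
#
# Example (commented out - supply your own validated thresholds):
# rules:
#   - rule_id: fibtem_low
#     parameter: fibtem_mcf_mm
#     op: lt
#     threshold: 8
#     action: fibrinogen-support
#     rationale: low fibrin-only clot firmness
rules: []
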