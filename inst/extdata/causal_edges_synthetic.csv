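source,target,polarity
no_financial_manager,liquidity_problems,1
liquidity_problems,weak_cost_analysis,1
weak_cost_analysis,no_financial_manager,1
weak_financial_analysis,liquidity_problems,1
liquidity_problems,weak_financial_analysis,1
poor_emergency_response,incorrect_prioritization,1
incorrect_prioritization,last_minute_procurement,1
last_minute_procurement,drug_shortages,-1
drug_shortages,poor_emergency_response,1
drug_shortages,last_minute_procurement,1
medication_expiration,medication_disposal,1
medication_disposal,low_profitability,1
low_profitability,weak_inventory_control,1
weak_inventory_control,medication_expiration,1
medication_expiration,weak_inventory_control,1
weak_consumption_analysis,inventory_problems,1
inventory_problems,weak_consumption_analysis,1
low_profitability,weak_recruitment,1
weak_recruitment,insufficient_hr,1
insufficient_hr,low_profitability,1
resident_overprescription,medication_expiration,1
insufficient_hr,poor_emergency_response,1
inventory_problems,liquidity_problems,1
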