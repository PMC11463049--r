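label,cycle,polarity
B1,drug_shortages;poor_emergency_response;incorrect_prioritization;last_minute_procurement,balancing
B2,drug_shortages;last_minute_procurement,balancing
R1,liquidity_problems;weak_cost_analysis;no_financial_manager,reinforcing
R2,liquidity_problems;weak_financial_analysis,reinforcing
R3,low_profitability;weak_inventory_control;medication_expiration;medication_disposal,reinforcing
R4,medication_expiration;weak_inventory_control,reinforcing
R5,inventory_problems;weak_consumption_analysis,reinforcing
R6,insufficient_hr;low_profitability;weak_recruitment,reinforcing
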