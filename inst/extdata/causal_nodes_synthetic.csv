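id,label,role
insufficient_hr,Insufficient specialized human resources,cause
poor_emergency_response,Poor responsiveness in emergencies,cause
resident_overprescription,Unnecessary prescription of drugs by residents,cause
weak_financial_analysis,Weakness in financial analysis,cause
medication_expiration,Expiration of certain medications,effect
incorrect_prioritization,Incorrect prioritization in drug procurement,cause
last_minute_procurement,Last-minute procurement of urgently needed drugs,effect
weak_consumption_analysis,Weak analysis of drug consumption patterns,cause
inventory_problems,Problems purchasing and maintaining drug inventory,effect
liquidity_problems,Inadequate liquidity management,effect
weak_cost_analysis,Insufficient cost-profitability analysis,cause
no_financial_manager,Lack of a certified financial manager,cause
low_profitability,Low pharmacy profitability,effect
weak_recruitment,Weak recruitment and retention of personnel,effect
medication_disposal,Disposal of expired medicines,effect
drug_shortages,Shortages of high-consumption drugs,cause
weak_inventory_control,Weak inventory control procedures,cause
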