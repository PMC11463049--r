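{
  "initial_profit": 0,
  "initial_residents": 10,
  "initial_expiring_stock": 2444,
  "initial_disposed_total": 0,
  "initial_inventory_high": 800,
  "workforce_competence": 1.0,
  "pharmacists_in_team": 2,
  "response_speed_base": 1.0,
  "accuracy_adjust_time": 2.0,
  "avg_price_low": 50,
  "profit_margin_low": 0.25,
  "profit_margin_high": 0.2,
  "disposal_unit_cost": 1.5,
  "avg_salary": 150,
  "staff_count": 8,
  "overhead_cost": 600,
  "expiry_inflow_base": 140,
  "resident_overprescription_coeff": 32,
  "expiry_fraction": 0.08,
  "transfer_rate_coeff": 0.05,
  "monthly_purchase": 1000,
  "share_high_consumption": 0.6,
  "order_delay": 1.0,
  "demand_high_base": 600,
  "demand_seasonal_amplitude": 0.25,
  "demand_period": 12,
  "resident_intake_rate": 1.0,
  "residency_duration": 48
}
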