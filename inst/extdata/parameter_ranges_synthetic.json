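{
  "initial_profit": {
    "dist": "uniform",
    "low": 0,
    "high": 2000
  },
  "initial_residents": {
    "dist": "uniform",
    "low": 7.5,
    "high": 12.5
  },
  "initial_expiring_stock": {
    "dist": "loguniform",
    "low": 1833,
    "high": 3055
  },
  "initial_disposed_total": {
    "dist": "uniform",
    "low": 0,
    "high": 100
  },
  "initial_inventory_high": {
    "dist": "loguniform",
    "low": 600,
    "high": 1000
  },
  "workforce_competence": {
    "dist": "uniform",
    "low": 0.75,
    "high": 1.25
  },
  "pharmacists_in_team": {
    "dist": "uniform",
    "low": 1.5,
    "high": 2.5
  },
  "response_speed_base": {
    "dist": "uniform",
    "low": 0.75,
    "high": 1.25
  },
  "accuracy_adjust_time": {
    "dist": "loguniform",
    "low": 1.5,
    "high": 2.5
  },
  "avg_price_low": {
    "dist": "loguniform",
    "low": 37.5,
    "high": 62.5
  },
  "profit_margin_low": {
    "dist": "uniform",
    "low": 0.1875,
    "high": 0.3125
  },
  "profit_margin_high": {
    "dist": "uniform",
    "low": 0.15,
    "high": 0.25
  },
  "disposal_unit_cost": {
    "dist": "loguniform",
    "low": 1.125,
    "high": 1.875
  },
  "avg_salary": {
    "dist": "loguniform",
    "low": 112.5,
    "high": 187.5
  },
  "staff_count": {
    "dist": "uniform",
    "low": 6,
    "high": 10
  },
  "overhead_cost": {
    "dist": "loguniform",
    "low": 450,
    "high": 750
  },
  "expiry_inflow_base": {
    "dist": "loguniform",
    "low": 105,
    "high": 175
  },
  "resident_overprescription_coeff": {
    "dist": "loguniform",
    "low": 24,
    "high": 40
  },
  "expiry_fraction": {
    "dist": "loguniform",
    "low": 0.06,
    "high": 0.1
  },
  "transfer_rate_coeff": {
    "dist": "loguniform",
    "low": 0.0375,
    "high": 0.0625
  },
  "monthly_purchase": {
    "dist": "loguniform",
    "low": 750,
    "high": 1250
  },
  "share_high_consumption": {
    "dist": "uniform",
    "low": 0.45,
    "high": 0.75
  },
  "order_delay": {
    "dist": "loguniform",
    "low": 0.75,
    "high": 1.25
  },
  "demand_high_base": {
    "dist": "loguniform",
    "low": 450,
    "high": 750
  },
  "demand_seasonal_amplitude": {
    "dist": "uniform",
    "low": 0.1875,
    "high": 0.3125
  },
  "demand_period": {
    "dist": "loguniform",
    "low": 9,
    "high": 15
  },
  "resident_intake_rate": {
    "dist": "loguniform",
    "low": 0.75,
    "high": 1.25
  },
  "residency_duration": {
    "dist": "loguniform",
    "low": 36,
    "high": 60
  }
}
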