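{
  "pdi": {
    "healthy_plant": ["wholegrains", "fruits", "vegetables", "nuts_seeds",
                      "legumes", "vegetable_oils", "tea_coffee"],
    "less_healthy_plant": ["fruit_juices", "refined_grains", "potatoes",
                           "sugar_sweetened_beverages", "sweets_desserts"],
    "animal": ["red_meat", "processed_meat", "poultry", "fish_seafood",
               "eggs", "dairy"]
  },
  "dash": {
    "encouraged": [
      {"name": "fruits", "groups": ["fruits"]},
      {"name": "vegetables", "groups": ["vegetables"]},
      {"name": "nuts_legumes", "groups": ["nuts_seeds", "legumes"]},
      {"name": "wholegrains", "groups": ["wholegrains"]},
      {"name": "low_fat_dairy", "groups": ["low_fat_dairy"]}
    ],
    "discouraged": [
      {"name": "red_processed_meat", "groups": ["red_meat", "processed_meat"]},
      {"name": "sugar_sweetened_beverages",
       "groups": ["sugar_sweetened_beverages"]},
      {"name": "sodium", "nutrient": "sodium_mg"}
    ]
  },
  "amed": {
    "beneficial": [
      {"name": "vegetables", "groups": ["vegetables"]},
      {"name": "fruits", "groups": ["fruits"]},
      {"name": "nuts_seeds", "groups": ["nuts_seeds"]},
      {"name": "legumes", "groups": ["legumes"]},
      {"name": "wholegrains", "groups": ["wholegrains"]},
      {"name": "fish_seafood", "groups": ["fish_seafood"]},
      {"name": "vegetable_oils", "groups": ["vegetable_oils"]}
    ],
    "adverse": [
      {"name": "red_processed_meat", "groups": ["red_meat", "processed_meat"]}
    ],
    "alcohol": {
      "group": "alcoholic_beverages",
      "window_female": [5, 15],
      "window_male": [10, 25]
    }
  },
  "plant_meat": {
    "plant": ["fruits", "vegetables", "wholegrains", "refined_grains",
              "legumes", "nuts_seeds", "potatoes", "sweets_desserts",
              "sugar_sweetened_beverages", "fruit_juices", "tea_coffee",
              "vegetable_oils"],
    "meat": ["red_meat", "processed_meat", "poultry", "fish_seafood"]
  }
}
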