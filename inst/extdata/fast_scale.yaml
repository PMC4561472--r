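items:
- id: item1
  label: No square meals
  text: In the past 6 months, how often did you eat three 'square meals' (full stomach
    meals) a day (not a festival day)?
- id: item2
  label: Have to eat other grains
  text: In the past 6 months, how often did you or any of your family have to eat
    wheat (or another grain) although you wanted to eat rice (not including when you
    were sick)?
- id: item3
  label: Skip entire meals
  text: In the past 6 months, how often did you yourself skip entire meals due to
    scarcity of food?
- id: item4
  label: Eat less
  text: In the past 6 months, how often did you personally eat less food in a meal
    due to scarcity of food?
- id: item5
  label: Run out of food
  text: In the past 6 months, how often did food stored in your home run out and there
    was no money to buy more that day?
- id: item6
  label: Worry about food
  text: In the past 6 months, how often did you worry about where food would come
    from?
- id: item7
  label: Purchase rice often
  text: In the past 6 months, how often did your family purchase rice?
- id: item8
  label: Take food on credit
  text: In the past 6 months, how often did your family take food (rice, lentils etc.)
    on credit (or loan) from a local shop?
- id: item9
  label: Borrow food
  text: In the past 6 months, how often did your family have to borrow food from relatives
    or neighbors to make a meal?
n_categories:
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
reverse_coded:
- item1
category_labels:
- never
- rarely
- sometimes
- often
- mostly
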