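# Ingredient-class lexicon: one synonym list per class. Matching is
# case-insensitive on normalized tokens, longest phrase wins. Edit or replace
# via the `lexicon` argument of the categorization functions.
schema_version: 1
classes:
  dairy:
    - milk
    - whole milk
    - skimmed milk
    - milk solids
    - milk powder
    - yogurt
    - yoghurt
    - greek yogurt
    - fromage frais
    - custard
    - cream
    - creme fraiche
    - buttermilk
    - rice pudding
  fruit:
    - fruit
    - apple
    - banana
    - pear
    - mango
    - peach
    - apricot
    - strawberry
    - raspberry
    - blueberry
    - blackcurrant
    - grape
    - raisin
    - date
    - prune
    - plum
    - pineapple
    - papaya
    - guava
    - orange
    - kiwi
    - melon
    - watermelon
    - coconut
    - cherry
    - lychee
    - dragon fruit
    - passion fruit
  vegetable:
    - vegetable
    - carrot
    - tomato
    - courgette
    - zucchini
    - pumpkin
    - squash
    - butternut squash
    - butternut
    - cauliflower
    - broccoli
    - spinach
    - kale
    - sweet potato
    - potato
    - sweetcorn
    - corn kernels
    - parsnip
    - beetroot
    - onion
    - leek
    - celery
    - cucumber
    - bell pepper
    - capsicum
    - green bean
    - green beans
    - cabbage
    - bok choy
    - mushroom
    - taro
  legume:
    - pea
    - peas
    - lentil
    - lentils
    - chickpea
    - chickpeas
    - bean
    - beans
    - red bean
    - mung bean
    - soybean
    - soy bean
    - edamame
    - tofu
  cereal:
    - rice
    - brown rice
    - jasmine rice
    - pasta
    - macaroni
    - noodle
    - noodles
    - oat
    - oats
    - oatmeal
    - wheat
    - wheat flour
    - barley
    - maize
    - cornmeal
    - corn flour
    - semolina
    - millet
    - couscous
    - bread
    - rye
  pseudocereal:
    - quinoa
    - chia
    - chia seed
    - buckwheat
    - amaranth
  meat:
    - meat
    - chicken
    - beef
    - pork
    - lamb
    - turkey
    - duck
    - veal
    - ham
    - liver
    - mutton
  fish:
    - fish
    - salmon
    - cod
    - tuna
    - sardine
    - mackerel
    - anchovy
    - haddock
    - pollock
    - tilapia
    - sea bass
    - shrimp
    - prawn
  cheese:
    - cheese
    - cheesy
    - cheddar
    - parmesan
    - mozzarella
    - ricotta
    - gouda
    - edam
  water:
    - water
    - added water
    - cooking water
  oil_fat:
    - oil
    - rapeseed oil
    - sunflower oil
    - olive oil
    - vegetable oil
    - canola oil
    - coconut oil
    - palm oil
    - butter
  sugar_sweetener:
    - sugar
    - cane sugar
    - brown sugar
    - honey
    - syrup
    - glucose syrup
    - fructose
    - glucose
    - sucrose
    - dextrose
    - maltodextrin
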