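day
time
week
month
year
house
thing
things
work
walk
talk
food
sleep
night
place
street
store
phone
bus
car
shop
cook
read
watch
door
room
bed
rest
home
town
park
game
show
news
book
desk
chair
floor
wall
yard
bird
tree
rain
sun
shoes
coat
bag
train
lunch
plate
cup
glass
bread
rice
soup
meat
fish
milk
juice
clock
light
lamp
porch
stairs
road
mall
bank
church
gym
pool
beach
hill
lake
note
list
plan
trip
ride
seat
line
card
cash
coin
bill
mail
box
key
lock
yarn
cloth
shirt
pants
socks
hat
morning
today
people
doctor
sister
brother
mother
father
dinner
breakfast
garden
window
music
weather
city
money
water
coffee
table
paper
letter
picture
sometimes
often
maybe
after
before
around
evening
apartment
neighbor
kitchen
corner
market
station
ticket
program
visit
visitor
moment
minute
number
building
sidewalk
laundry
grocery
blanket
pillow
curtain
carpet
cousin
uncle
auntie
nephew
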